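# The published chordate oral secondary-sensory-cell matrix: 16 tunicates
# plus four outgroup species (a cephalochordate and three vertebrates) scored
# for 19 binary characters describing coronal-organ / circumoral-ring
# morphology. The printed row for Oikopleura dioica stops at character 18;
# character 19 is encoded as missing (see the package vignette for the
# sensitivity check on that cell).

.CORONAL_TAXA <- c(
  "Botryllus schlosseri",
  "Botrylloides leachi",
  "Styela plicata",
  "Polyandrocarpa zorritensis",
  "Molgula socialis",
  "Pyura stolonifera",
  "Clavelina lepadiformis",
  "Diplosoma listerianum",
  "Ciona intestinalis",
  "Ascidiella aspersa",
  "Phallusia mammillata",
  "Chelyosoma productum",
  "Corella inflata",
  "Oikopleura dioica",
  "Pyrosoma atlanticum",
  "Doliolum nationalis",
  "Branchiostoma floridae",
  "Lethenteron camtschaticum",
  "Eptatretus stoutii",
  "Danio rerio"
)

.CORONAL_ROWS <- c(
  "0 1 0 0 - 1 1 0 1 - - 0 1 0 0 1 1 0 1",
  "0 1 0 0 - 1 1 0 1 - - 0 1 0 0 1 1 0 1",
  "0 1 1 0 0 1 1 0 0 - - 0 1 1 0 1 1 0 1",
  "0 1 1 0 0 1 1 0 0 - - 0 1 1 0 1 1 0 1",
  "0 1 1 0 0 1 1 0 0 - - 0 1 1 1 1 1 1 1",
  "0 1 1 0 0 1 1 0 0 - - 0 1 1 1 1 1 1 1",
  "1 0 0 1 0 1 - - - 1 0 0 1 0 0 0 1 0 1",
  "1 0 0 1 0 1 - - - 0 0 0 1 0 0 0 1 0 1",
  "1 0 0 1 0 1 - - - 1 0 0 0 0 0 1 1 0 1",
  "1 0 0 1 0 1 - - - 1 0 1 0 0 0 0 1 0 1",
  "1 0 0 1 0 0 - - - - 0 0 0 1 0 0 1 0 1",
  "1 0 0 1 0 1 - - - 1 0 1 0 0 0 0 1 0 1",
  "1 0 0 1 0 0 - - - - 0 1 0 0 0 0 1 0 1",
  "1 0 0 1 1 0/1 - - - 1 1 0 1 0 0 0 0 - ?",
  "1 1 0 0 - 1 1 0 0 - - 0 0 0 ? 0 1 0 1",
  "1 1 0 0 - 1 1 0 0 - - 0 0 0 0 0 1 0 1",
  "1 1 0 0 - 1 0 0 0 - - 0 0 0 - 1 1 0 0",
  "1 1 0 0 - 1 0 1 - - - 0 0 0 - 0 0 - 0",
  "1 1 0 0 - 1 1 0 - - - 0 0 0 - ? 0 - 0",
  "1 1 0 0 - 1 0 1 - - - 0 0 0 - ? 0 - 0"
)

.CORONAL_DEFINITIONS <- c(
  "Single type of secondary sensory cells (present = 1, absent = 0)",
  "Secondary sensory cells with a single cilium (monociliary) (present = 1, absent = 0)",
  "Secondary sensory cells with two cilia (biciliary) (present = 1, absent = 0)",
  "Secondary sensory cells with more than two cilia (multiciliary) (present = 1, absent = 0)",
  "Cilia in multiciliary sensory cells of same length (0) / different lengths (1)",
  "Microvilli or stereovilli on sensory cells (present = 1, absent = 0)",
  "Microvilli on monociliary sensory cells (present = 1, absent = 0)",
  "Stereovilli on monociliary sensory cells (present = 1, absent = 0)",
  "Cilium of monociliary sensory cell surrounded by a ring of microvilli (0) or cilium eccentric to microvilli (1)",
  "Microvilli on multiciliary sensory cells (present = 1, absent = 0)",
  "Cilia in multiciliary sensory cells in a single line (0) or in multiple lines (1)",
  "Accessory secretory cells in coronal organ (present = 1, absent = 0)",
  "Supporting cells form a wall or crest alongside the coronal organ (present = 1, absent = 0)",
  "Electron dense granules in sensory cells (present = 1, absent = 0)",
  "Width of coronal organ uniform along oral rim (0) or wider at certain areas (1)",
  "Accessory centriole in sensory cells (present = 1, absent = 0)",
  "Tentacles or flaps present (present = 1, absent = 0)",
  "Tentacles simple (0) / branched (1)",
  "Secondary sensory cells in continuous row (present = 1, absent = 0)"
)

#' The chordate oral secondary-sensory-cell character matrix
#'
#' Returns the published 20-taxon x 19-character binary matrix of oral
#' secondary-sensory-cell (coronal organ / circumoral ring) morphology: 16
#' tunicate species plus the outgroups *Branchiostoma floridae*,
#' *Lethenteron camtschaticum*, *Eptatretus stoutii* and *Danio rerio*.
#' Character definitions are carried in the character table. Cells are coded
#' `0`/`1` with `?` for missing, `-` for inapplicable and `0/1` for an
#' uncertain cell (character 6 of *Oikopleura dioica*). The printed source
#' row for *O. dioica* lacks a value for character 19, which is therefore
#' coded missing; `oikopleura_19` substitutes an explicit state for that cell
#' (the species' circumoral ring is continuous, suggesting state 1) for
#' sensitivity analysis.
#'
#' @param oikopleura_19 symbol for the unprinted *O. dioica* character-19
#'   cell: `"?"` (default, missing) or `"0"`/`"1"`.
#' @return a [char_matrix] with 20 taxa and 19 characters.
#' @examples
#' m <- coronal_matrix()
#' n_taxa(m)
#' @export
coronal_matrix <- function(oikopleura_19 = "?") {
  stopifnot(oikopleura_19 %in% c("?", "0", "1"))
  rows <- .CORONAL_ROWS
  x <- do.call(rbind, strsplit(rows, " ", fixed = TRUE))
  rownames(x) <- .CORONAL_TAXA
  x["Oikopleura dioica", 19] <- oikopleura_19
  char_matrix(x, definitions = .CORONAL_DEFINITIONS)
}

#' @rdname coronal_matrix
#' @details `coronal_outgroups()` returns the four outgroup species used to
#'   root trees for display and for ancestral-state reconstruction.
#' @export
coronal_outgroups <- function() {
  c("Branchiostoma floridae", "Lethenteron camtschaticum",
    "Eptatretus stoutii", "Danio rerio")
}
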