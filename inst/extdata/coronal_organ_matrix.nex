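#NEXUS

BEGIN TAXA;
  DIMENSIONS NTAX=20;
  TAXLABELS
    'Botryllus schlosseri'
    'Botrylloides leachi'
    'Styela plicata'
    'Polyandrocarpa zorritensis'
    'Molgula socialis'
    'Pyura stolonifera'
    'Clavelina lepadiformis'
    'Diplosoma listerianum'
    'Ciona intestinalis'
    'Ascidiella aspersa'
    'Phallusia mammillata'
    'Chelyosoma productum'
    'Corella inflata'
    'Oikopleura dioica'
    'Pyrosoma atlanticum'
    'Doliolum nationalis'
    'Branchiostoma floridae'
    'Lethenteron camtschaticum'
    'Eptatretus stoutii'
    'Danio rerio'
  ;
END;

BEGIN CHARACTERS;
  DIMENSIONS NCHAR=19;
  FORMAT DATATYPE=STANDARD SYMBOLS="01" MISSING=? GAP=-;
  CHARSTATELABELS
    1 'Single type of secondary sensory cells (present = 1, absent = 0)',
    2 'Secondary sensory cells with a single cilium (monociliary) (present = 1, absent = 0)',
    3 'Secondary sensory cells with two cilia (biciliary) (present = 1, absent = 0)',
    4 'Secondary sensory cells with more than two cilia (multiciliary) (present = 1, absent = 0)',
    5 'Cilia in multiciliary sensory cells of same length (0) / different lengths (1)',
    6 'Microvilli or stereovilli on sensory cells (present = 1, absent = 0)',
    7 'Microvilli on monociliary sensory cells (present = 1, absent = 0)',
    8 'Stereovilli on monociliary sensory cells (present = 1, absent = 0)',
    9 'Cilium of monociliary sensory cell surrounded by a ring of microvilli (0) or cilium eccentric to microvilli (1)',
    10 'Microvilli on multiciliary sensory cells (present = 1, absent = 0)',
    11 'Cilia in multiciliary sensory cells in a single line (0) or in multiple lines (1)',
    12 'Accessory secretory cells in coronal organ (present = 1, absent = 0)',
    13 'Supporting cells form a wall or crest alongside the coronal organ (present = 1, absent = 0)',
    14 'Electron dense granules in sensory cells (present = 1, absent = 0)',
    15 'Width of coronal organ uniform along oral rim (0) or wider at certain areas (1)',
    16 'Accessory centriole in sensory cells (present = 1, absent = 0)',
    17 'Tentacles or flaps present (present = 1, absent = 0)',
    18 'Tentacles simple (0) / branched (1)',
    19 'Secondary sensory cells in continuous row (present = 1, absent = 0)'
  ;
  MATRIX
    'Botryllus schlosseri'        0100-1101--01001101
    'Botrylloides leachi'         0100-1101--01001101
    'Styela plicata'              011001100--01101101
    'Polyandrocarpa zorritensis'  011001100--01101101
    'Molgula socialis'            011001100--01111111
    'Pyura stolonifera'           011001100--01111111
    'Clavelina lepadiformis'      100101---1001000101
    'Diplosoma listerianum'       100101---0001000101
    'Ciona intestinalis'          100101---1000001101
    'Ascidiella aspersa'          100101---1010000101
    'Phallusia mammillata'        100100----000100101
    'Chelyosoma productum'        100101---1010000101
    'Corella inflata'             100100----010000101
    'Oikopleura dioica'           10011(01)---11010000-?
    'Pyrosoma atlanticum'         1100-1100--000?0101
    'Doliolum nationalis'         1100-1100--00000101
    'Branchiostoma floridae'      1100-1000--000-1100
    'Lethenteron camtschaticum'   1100-101---000-00-0
    'Eptatretus stoutii'          1100-110---000-?0-0
    'Danio rerio'                 1100-101---000-?0-0
  ;
END;

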