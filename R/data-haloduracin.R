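#' Haloduracin A2 core peptide sequence
#'
#' The core region of the haloduracin beta precursor peptide (HalA2) from
#' *Bacillus halodurans*, as established in the lanthipeptide literature.
#' The core carries eight Ser/Thr residues, of which seven are dehydrated by
#' HalM2 during maturation. Tag-removal proteolysis with TEV protease leaves
#' one extra N-terminal glycine on the released core
#' (see `paste0("G", hala2_core)`).
#'
#' @format A single string of one-letter residue codes (24 residues).
#' @export
hala2_core <- "TTWPCATVGVSVALCPTTKCTSQC"
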