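#' Path to the packaged signaling-network transcription
#'
#' The packaged network is a synthetic transcription of the
#' GPR30/EGFR/PI3K/MAPK/STAT reaction network: a reaction-table TSV
#' (`signaling_network_synthetic.tsv`) plus a companion species table
#' (`signaling_species_synthetic.tsv`) reconstructed from the published
#' pathway description, with rate constants chosen by this package (see the
#' methods vignette). It comprises 128 species, 143 reactions, 213
#' parameters and 1 rule (the tamoxifen-input clamp).
#'
#' @param which `"reactions"` or `"species"`.
#' @return Path to the installed TSV file.
#' @export
signaling_network_path <- function(which = c("reactions", "species")) {
  which <- match.arg(which)
  fname <- switch(which,
                  reactions = "signaling_network_synthetic.tsv",
                  species = "signaling_species_synthetic.tsv")
  path <- system.file("extdata", fname, package = "gpersig")
  if (!nzchar(path)) stop("packaged network file not found: ", fname)
  path
}

#' Build the full GPR30/EGFR/PI3K/MAPK/STAT model
#'
#' Assembles the packaged synthetic network transcription under one of the
#' two study conditions. Both conditions share the identical reaction
#' network and stoichiometry; they differ only in the ligand inputs: the
#' treated condition clamps the tamoxifen input at `tam_dose`, the
#' untreated condition at 0. The tamoxifen clamp is implemented as the
#' model's single assignment rule (`Tam = Tam_dose`), so the sensitivity of
#' any observable to the tamoxifen input can be probed through the
#' `Tam_dose` parameter.
#'
#' @param condition `"treated"` or `"untreated"`.
#' @param tam_dose Clamped tamoxifen concentration for the treated
#'   condition, uM (default 1).
#' @param egf0 Initial free-EGF concentration shared by both conditions, uM
#'   (default 5e-4, a low autocrine baseline).
#' @return A validated `sig_model` with 128 species, 143 reactions, 213
#'   parameters and 1 rule.
#' @export
build_full_model <- function(condition = c("treated", "untreated"),
                             tam_dose = 1, egf0 = 5e-4) {
  condition <- match.arg(condition)
  rows <- parse_reaction_table(signaling_network_path("reactions"))
  st <- read_species_table(signaling_network_path("species"))
  dose <- if (condition == "treated") tam_dose else 0
  cond <- condition_spec(condition, c(Tam = dose, EGF = egf0))
  assemble_model(rows, cond, species_table = st, clamp = "Tam",
                 name = paste0("gper_signaling_", condition))
}

#' Standard observables of the full model
#'
#' Returns the four headline observables used in treated-versus-untreated
#' comparison and sensitivity ranking: ppERK (all doubly-phosphorylated-ERK
#' pools, free, complexed and nuclear), ppMEK, Raf1_active and PI3K_active,
#' each assembled from species tags.
#'
#' @param model A full model from [build_full_model()].
#' @return Named list of [observable()]s.
#' @export
full_model_observables <- function(model) {
  nm <- c("ppERK", "ppMEK", "Raf1_active", "PI3K_active")
  stats::setNames(lapply(nm, function(n) observable_from_tags(model, n)), nm)
}
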