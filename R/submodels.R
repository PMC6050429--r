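#' Canonical pathway submodels
#'
#' Self-contained, simulable mass-action models of the signaling motifs the
#' full network is built from. Default rate constants are order-of-magnitude
#' choices within the unit convention (first-order 1e-3..1 /s, second-order
#' 1e-3..1 /(uM s)); the motifs exist for property testing and didactics,
#' not quantitative prediction.
#'
#' Available motifs:
#' \describe{
#'   \item{egfr_activation}{Ligand binding, receptor dimerization (explicit
#'     2-to-1 stoichiometry) and autophosphorylation.}
#'   \item{ras_raf_mek_erk}{Three-tier MAPK cascade with dual (distributive)
#'     MEK and ERK phosphorylation, driven by a decaying input bolus, so the
#'     ppERK response is a transient pulse.}
#'   \item{pi3k_akt_pten}{PIP2/PIP3 turnover with PTEN antagonism and
#'     membrane recruitment of Akt (reversible Akt + PIP3 binding).}
#'   \item{jak_stat}{Receptor-mediated STAT phosphorylation, dimerization
#'     and nuclear translocation with recycling.}
#'   \item{gpr30_plc_pkc}{Ligand-activated GPCR releasing Gbg, PLC
#'     activation, IP3/DAG production and PKC activation.}
#'   \item{src_mmp_hbegf}{Gbg-driven Src activation, MMP maturation and
#'     HB-EGF shedding releasing free EGF (transactivation arm).}
#'   \item{gpcr_internalization}{GRK phosphorylation, beta-arrestin capture,
#'     internalization and recycling; the receptor moiety is conserved.}
#' }
#'
#' @param name One of the motif names above.
#' @return A validated `sig_model`.
#' @export
build_submodel <- function(name) {
  builders <- list(
    egfr_activation = submodel_egfr_activation,
    ras_raf_mek_erk = submodel_ras_raf_mek_erk,
    pi3k_akt_pten = submodel_pi3k_akt_pten,
    jak_stat = submodel_jak_stat,
    gpr30_plc_pkc = submodel_gpr30_plc_pkc,
    src_mmp_hbegf = submodel_src_mmp_hbegf,
    gpcr_internalization = submodel_gpcr_internalization
  )
  if (!name %in% names(builders)) {
    stop("unknown submodel '", name, "'; available: ",
         paste(names(builders), collapse = ", "))
  }
  builders[[name]]()
}

submodel_egfr_activation <- function() {
  sp <- list(
    species("EGF", initial_concentration = 0.1, is_boundary = TRUE),
    species("EGFR", initial_concentration = 0.5),
    species("EGFR_EGF"),
    species("EGFR2"),
    species("EGFR2_p", tags = "observable:active_receptor")
  )
  rx <- list(
    reaction("bind", c(EGF = 1, EGFR = 1), c(EGFR_EGF = 1), kf = 1, kr = 0.1),
    reaction("dimerize", c(EGFR_EGF = 2), c(EGFR2 = 1), kf = 0.5, kr = 0.01),
    reaction("autophos", c(EGFR2 = 1), c(EGFR2_p = 1), kf = 0.1),
    reaction("dephos", c(EGFR2_p = 1), c(EGFR2 = 1), kf = 0.01)
  )
  sig_model("egfr_activation", sp, rx, condition_label = "motif")
}

submodel_ras_raf_mek_erk <- function(input_level = 0.1) {
  sp <- list(
    species("Input", initial_concentration = input_level),
    species("Raf", initial_concentration = 0.5),
    species("Raf_act", tags = "observable:Raf1_active"),
    species("MEK", initial_concentration = 0.5),
    species("MEK_p"),
    species("MEK_pp", tags = "observable:ppMEK"),
    species("ERK", initial_concentration = 0.5),
    species("ERK_p"),
    species("ERK_pp", tags = "observable:ppERK")
  )
  rx <- list(
    reaction("input_decay", c(Input = 1), c(), kf = 0.002),
    reaction("raf_act", c(Raf = 1, Input = 1), c(Raf_act = 1, Input = 1), kf = 1),
    reaction("raf_deact", c(Raf_act = 1), c(Raf = 1), kf = 0.05),
    reaction("mek_p1", c(MEK = 1, Raf_act = 1), c(MEK_p = 1, Raf_act = 1), kf = 1),
    reaction("mek_p2", c(MEK_p = 1, Raf_act = 1), c(MEK_pp = 1, Raf_act = 1), kf = 1),
    reaction("mek_dp2", c(MEK_pp = 1), c(MEK_p = 1), kf = 0.05),
    reaction("mek_dp1", c(MEK_p = 1), c(MEK = 1), kf = 0.05),
    reaction("erk_p1", c(ERK = 1, MEK_pp = 1), c(ERK_p = 1, MEK_pp = 1), kf = 1),
    reaction("erk_p2", c(ERK_p = 1, MEK_pp = 1), c(ERK_pp = 1, MEK_pp = 1), kf = 1),
    reaction("erk_dp2", c(ERK_pp = 1), c(ERK_p = 1), kf = 0.05),
    reaction("erk_dp1", c(ERK_p = 1), c(ERK = 1), kf = 0.05)
  )
  sig_model("ras_raf_mek_erk", sp, rx, condition_label = "motif")
}

submodel_pi3k_akt_pten <- function(pten_rate = 0.5) {
  sp <- list(
    species("PI3K_act", initial_concentration = 0.05, is_boundary = TRUE),
    species("PIP2", initial_concentration = 5),
    species("PIP3", tags = "observable:PIP3"),
    species("PTEN", initial_concentration = 0.2),
    species("Akt", initial_concentration = 0.5),
    species("Aktm", tags = "observable:Akt_membrane")
  )
  rx <- list(
    reaction("pip3_prod", c(PIP2 = 1, PI3K_act = 1), c(PIP3 = 1, PI3K_act = 1),
             kf = 0.2),
    reaction("pip3_deg", c(PIP3 = 1, PTEN = 1), c(PIP2 = 1, PTEN = 1),
             kf = pten_rate),
    # reversible membrane recruitment: Akt + PIP3 <-> Aktm
    reaction("akt_recruit", c(Akt = 1, PIP3 = 1), c(Aktm = 1), kf = 0.05, kr = 0.5)
  )
  sig_model("pi3k_akt_pten", sp, rx, condition_label = "motif")
}

submodel_jak_stat <- function() {
  sp <- list(
    species("R_act", initial_concentration = 0.1, is_boundary = TRUE),
    species("STAT", initial_concentration = 1),
    species("R_STAT"),
    species("STAT_p"),
    species("STAT_dim", tags = "observable:STAT_dimer"),
    species("STAT_dim_n", tags = "observable:STAT_dimer")
  )
  rx <- list(
    reaction("stat_bind", c(STAT = 1, R_act = 1), c(R_STAT = 1), kf = 0.5, kr = 0.1),
    reaction("stat_phos", c(R_STAT = 1), c(STAT_p = 1), kf = 0.2),
    reaction("stat_dim", c(STAT_p = 2), c(STAT_dim = 1), kf = 0.5, kr = 0.05),
    reaction("dim_import", c(STAT_dim = 1), c(STAT_dim_n = 1), kf = 0.01),
    reaction("dim_recycle", c(STAT_dim_n = 1), c(STAT = 2), kf = 0.002)
  )
  # note stat_phos releases STAT_p but keeps R_act clamped; R_STAT -> STAT_p
  # implicitly returns the receptor which is boundary anyway
  sig_model("jak_stat", sp, rx, condition_label = "motif")
}

submodel_gpr30_plc_pkc <- function() {
  sp <- list(
    species("Tam", initial_concentration = 1, is_boundary = TRUE),
    species("GPR30", initial_concentration = 0.3),
    species("GPR30_Tam"),
    species("Gbg_i", initial_concentration = 0.5),
    species("Gbg"),
    species("PLC", initial_concentration = 0.3),
    species("PLC_act"),
    species("PIP2", initial_concentration = 5),
    species("IP3"),
    species("DAG"),
    species("PKC", initial_concentration = 0.5),
    species("PKC_DAG"),
    species("PKC_act", tags = "observable:active_PKC")
  )
  rx <- list(
    reaction("tam_bind", c(Tam = 1, GPR30 = 1), c(GPR30_Tam = 1), kf = 0.5, kr = 0.1),
    reaction("g_release", c(Gbg_i = 1, GPR30_Tam = 1), c(Gbg = 1, GPR30_Tam = 1),
             kf = 0.5),
    reaction("g_reform", c(Gbg = 1), c(Gbg_i = 1), kf = 0.05),
    reaction("plc_act", c(Gbg = 1, PLC = 1), c(PLC_act = 1), kf = 0.5, kr = 0.1),
    reaction("ip3_dag", c(PIP2 = 1, PLC_act = 1), c(IP3 = 1, DAG = 1, PLC_act = 1),
             kf = 0.1),
    reaction("ip3_deg", c(IP3 = 1), c(), kf = 0.02),
    reaction("dag_deg", c(DAG = 1), c(), kf = 0.02),
    reaction("pkc_dag", c(PKC = 1, DAG = 1), c(PKC_DAG = 1), kf = 0.5, kr = 0.1),
    reaction("pkc_act", c(PKC_DAG = 1, IP3 = 1), c(PKC_act = 1, IP3 = 1), kf = 0.5),
    reaction("pkc_deact", c(PKC_act = 1), c(PKC = 1), kf = 0.05)
  )
  sig_model("gpr30_plc_pkc", sp, rx, condition_label = "motif")
}

submodel_src_mmp_hbegf <- function() {
  sp <- list(
    species("Gbg", initial_concentration = 0.2, is_boundary = TRUE),
    species("Src", initial_concentration = 0.5),
    species("Src_act", tags = "observable:active_Src"),
    species("proMMP", initial_concentration = 0.5),
    species("MMP"),
    species("HBEGF_m", initial_concentration = 1, is_boundary = TRUE),
    species("EGF", tags = "observable:free_EGF")
  )
  rx <- list(
    reaction("src_act", c(Src = 1, Gbg = 1), c(Src_act = 1, Gbg = 1), kf = 0.5),
    reaction("src_deact", c(Src_act = 1), c(Src = 1), kf = 0.05),
    reaction("mmp_act", c(proMMP = 1, Src_act = 1), c(MMP = 1, Src_act = 1),
             kf = 0.5),
    reaction("mmp_deact", c(MMP = 1), c(proMMP = 1), kf = 0.05),
    reaction("shed", c(HBEGF_m = 1, MMP = 1), c(EGF = 1, MMP = 1), kf = 0.1),
    reaction("egf_deg", c(EGF = 1), c(), kf = 0.01)
  )
  sig_model("src_mmp_hbegf", sp, rx, condition_label = "motif")
}

submodel_gpcr_internalization <- function() {
  sp <- list(
    species("R", initial_concentration = 0.3),
    species("GRK", initial_concentration = 0.1),
    species("R_p"),
    species("bArr", initial_concentration = 0.2),
    species("R_p_bArr"),
    species("R_i_bArr"),
    species("R_i")
  )
  rx <- list(
    reaction("phos", c(R = 1, GRK = 1), c(R_p = 1, GRK = 1), kf = 0.5),
    reaction("arrestin_bind", c(R_p = 1, bArr = 1), c(R_p_bArr = 1),
             kf = 0.5, kr = 0.05),
    reaction("internalize", c(R_p_bArr = 1), c(R_i_bArr = 1), kf = 0.02),
    reaction("dissociate", c(R_i_bArr = 1), c(R_i = 1, bArr = 1), kf = 0.05),
    reaction("recycle", c(R_i = 1), c(R = 1), kf = 0.01)
  )
  sig_model("gpcr_internalization", sp, rx, condition_label = "motif")
}
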