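# Run expr with a locally seeded RNG, restoring the caller's RNG state.
# All generators derive their stream from (seed, label) so fixtures from
# different generators compose deterministically without sharing a stream.
with_seed <- function(seed, label, expr) {
  derived <- (as.numeric(seed) * 48271 + sum(utf8ToInt(label))) %% 2147483647
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(derived))
  force(expr)
}

new_truth <- function(generator, seed, payload) {
  structure(list(generator = generator, seed = seed, payload = payload),
            class = "sig_truth")
}

#' Generate a random mass-action network
#'
#' Draws a valid mass-action model with uni- and bimolecular reactions only:
#' reactant and product sets are sampled uniformly from the species pool,
#' rate constants log-uniformly from \[1e-3, 1\] (in 1/s or 1/(uM s)
#' according to order), and a fraction of the reactions is made reversible.
#' Initial concentrations are uniform on \[0.1, 2\] uM. Deterministic given
#' the seed.
#'
#' @param n_species Number of species (>= 2).
#' @param n_reactions Number of reactions (>= 1).
#' @param frac_reversible Expected fraction of reversible reactions.
#' @param seed Integer seed.
#' @return List with `model` (a `sig_model`) and `truth` (a `sig_truth`
#'   recording the generating stoichiometry and rate constants).
#' @export
random_network <- function(n_species = 8, n_reactions = 10,
                           frac_reversible = 0.3, seed = 1) {
  if (n_species < 2) stop("n_species must be >= 2")
  if (n_reactions < 1) stop("n_reactions must be >= 1")
  stopifnot(frac_reversible >= 0, frac_reversible <= 1)
  with_seed(seed, "random_network", {
    sids <- sprintf("X%02d", seq_len(n_species))
    sp <- lapply(sids, function(s) {
      species(s, initial_concentration = stats::runif(1, 0.1, 2))
    })
    rxns <- vector("list", n_reactions)
    for (j in seq_len(n_reactions)) {
      rev <- stats::runif(1) < frac_reversible
      n_r <- sample(1:2, 1)
      n_p <- if (rev) sample(1:2, 1) else sample(1:2, 1)
      r_sp <- sample(sids, n_r, replace = TRUE)
      repeat {
        p_sp <- sample(sids, n_p, replace = TRUE)
        if (!setequal(unique(p_sp), unique(r_sp)) ||
            !identical(sort(p_sp), sort(r_sp))) break
      }
      reactants <- table_to_stoich(r_sp)
      products <- table_to_stoich(p_sp)
      kf_val <- 10^stats::runif(1, -3, 0)
      kf <- rate_constant(sprintf("kf_R%02d", j), kf_val, sum(reactants))
      kr <- if (rev) {
        rate_constant(sprintf("kr_R%02d", j), 10^stats::runif(1, -3, 0),
                      sum(products))
      } else NULL
      rxns[[j]] <- reaction(sprintf("R%02d", j), reactants, products,
                            kf = kf, kr = kr, reversible = rev)
    }
    model <- sig_model(sprintf("random_network_seed%d", seed), sp, rxns,
                       condition_label = "synthetic")
    truth <- new_truth("random_network", seed, list(
      rate_constants = stats::setNames(
        unlist(lapply(rxns, function(r) {
          c(stats::setNames(r$kf$value, r$kf$id),
            if (!is.null(r$kr)) stats::setNames(r$kr$value, r$kr$id))
        })), NULL),
      stoichiometry = NULL
    ))
    truth$payload$stoichiometry <- stoichiometry_matrix(model)
    list(model = model, truth = truth)
  })
}

table_to_stoich <- function(tokens) {
  tb <- table(tokens)
  stats::setNames(as.integer(tb), names(tb))
}

#' Generate a noisy observable time course
#'
#' Integrates the model with the supplied true rate constants and corrupts
#' the observable with multiplicative lognormal noise of the requested
#' coefficient of variation. Deterministic given the seed.
#'
#' @param model A `sig_model`.
#' @param obs A [observable()].
#' @param true_params Named numeric vector of rate-constant values to
#'   install before simulating (may be empty to use the model as-is).
#' @param t_grid Times (seconds) at which data are generated.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0; 0 returns the clean trajectory).
#' @param seed Integer seed.
#' @return List with `times`, `values`, `clean` (noise-free values),
#'   `observable`, and `truth` (records `true_params` and `noise_cv`).
#' @export
noisy_timecourse <- function(model, obs, true_params = numeric(),
                             t_grid = seq(0, 600, length.out = 50),
                             noise_cv = 0.05, seed = 1) {
  stopifnot(noise_cv >= 0)
  m <- model
  for (id in names(true_params)) m <- set_quantity(m, id, true_params[[id]])
  n_pts <- max(200L, length(t_grid))
  tr <- integrate_model(m, t_end = max(t_grid), n_points = n_pts)
  y <- observable_timecourse(tr, obs)
  clean <- stats::approx(tr$times, y, xout = t_grid, rule = 2)$y
  values <- if (noise_cv == 0) clean else with_seed(seed, "noisy_timecourse", {
    sdlog <- sqrt(log(1 + noise_cv^2))
    clean * stats::rlnorm(length(clean), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  })
  list(times = t_grid, values = values, clean = clean, observable = obs,
       truth = new_truth("noisy_timecourse", seed,
                         list(true_params = true_params, noise_cv = noise_cv)))
}

#' Generate a synthetic two-group count table with planted DEGs
#'
#' Emulates a treated-versus-untreated RNA-seq design: negative-binomial
#' counts (variance = mu + mu^2 * dispersion) around log-normal baseline
#' means, with `n_up` genes shifted up and `n_down` genes shifted down by
#' `effect_log2fc` in the treated group. Per-gene p-values are computed
#' internally by the exact Wilcoxon rank-sum test on the
#' library-size-normalized counts, so the downstream DEG-calling stage can
#' be tested end to end. The default of two samples per group matches a
#' two-biological-replicate design; note an exact rank test at 2 vs 2
#' cannot reach small p-values, so power studies should raise
#' `n_samples_per_group`.
#'
#' @param n_genes Number of genes.
#' @param n_samples_per_group Samples in each of the two groups (default 2).
#' @param n_up,n_down Numbers of planted up-/down-regulated genes
#'   (`n_up + n_down <= n_genes`).
#' @param effect_log2fc Planted absolute log2 fold change.
#' @param dispersion Negative-binomial dispersion d in var = mu + mu^2 d.
#' @param seed Integer seed.
#' @return List with `table` (a [count_table()]), `stats` (data frame
#'   `gene_id`, `log2fc`, `pvalue` ready for [call_degs()]), and `truth`
#'   (planted up/down gene ids).
#' @export
synthetic_counts <- function(n_genes = 1000, n_samples_per_group = 2,
                             n_up = 0, n_down = 0, effect_log2fc = 2,
                             dispersion = 0.05, seed = 1) {
  if (n_up + n_down > n_genes) stop("n_up + n_down must not exceed n_genes")
  stopifnot(n_genes >= 1, n_samples_per_group >= 2, dispersion > 0)
  with_seed(seed, "synthetic_counts", {
    genes <- sprintf("G%05d", seq_len(n_genes))
    up <- if (n_up > 0) genes[seq_len(n_up)] else character()
    down <- if (n_down > 0) genes[n_up + seq_len(n_down)] else character()
    base_mu <- stats::rlnorm(n_genes, meanlog = log(100), sdlog = 1)
    fc <- rep(1, n_genes)
    fc[genes %in% up] <- 2^effect_log2fc
    fc[genes %in% down] <- 2^(-effect_log2fc)
    ns <- n_samples_per_group
    mu_u <- matrix(base_mu, n_genes, ns)
    mu_t <- matrix(base_mu * fc, n_genes, ns)
    mu <- cbind(mu_u, mu_t)
    size <- 1 / dispersion
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = size),
                     n_genes, 2 * ns,
                     dimnames = list(genes, c(sprintf("untreated_%d", seq_len(ns)),
                                              sprintf("treated_%d", seq_len(ns)))))
    length_kb <- stats::runif(n_genes, 0.5, 10)
    mapped_millions <- colSums(counts) / 1e6
    tab <- count_table(counts, length_kb, mapped_millions)
    # normalize to counts-per-million before the rank test so library-size
    # differences do not masquerade as expression differences
    cpm <- sweep(counts, 2, colSums(counts) / 1e6, "/")
    grp <- rep(c("untreated", "treated"), each = ns)
    pvals <- apply(cpm, 1, function(x) {
      # exact rank-sum distribution; normal approximation under ties
      suppressWarnings(
        stats::wilcox.test(x[grp == "treated"], x[grp == "untreated"],
                           exact = TRUE)$p.value)
    })
    log2fc <- log2((rowMeans(cpm[, grp == "treated", drop = FALSE]) + 0.5) /
                     (rowMeans(cpm[, grp == "untreated", drop = FALSE]) + 0.5))
    list(table = tab,
         stats = data.frame(gene_id = genes, log2fc = log2fc, pvalue = pvals,
                            stringsAsFactors = FALSE, row.names = NULL),
         truth = new_truth("synthetic_counts", seed,
                           list(up = up, down = down,
                                effect_log2fc = effect_log2fc)))
  })
}

#' Generate gene sets with one planted enriched term
#'
#' Builds a background of `n_background` genes and `n_terms` random gene
#' sets of size `term_size`; the first term is designated enriched and its
#' members are oversampled into the gene list with weight `enrich_factor`
#' relative to non-members (factor 1 = null).
#'
#' @param n_background Background (universe) size.
#' @param n_terms Number of gene sets.
#' @param term_size Genes per set.
#' @param list_size Size of the gene list of interest.
#' @param enrich_factor Sampling weight of planted-term members (>= 1).
#' @param seed Integer seed.
#' @return List with `background`, `gene_sets` (named list), `gene_list`,
#'   and `truth` (the planted term id).
#' @export
planted_enrichment <- function(n_background = 5000, n_terms = 20,
                               term_size = 50, list_size = 100,
                               enrich_factor = 5, seed = 1) {
  stopifnot(term_size <= n_background, list_size <= n_background,
            enrich_factor >= 1, n_terms >= 1)
  with_seed(seed, "planted_enrichment", {
    background <- sprintf("BG%05d", seq_len(n_background))
    gene_sets <- stats::setNames(
      lapply(seq_len(n_terms), function(i) sample(background, term_size)),
      sprintf("TERM%03d", seq_len(n_terms))
    )
    planted <- "TERM001"
    w <- rep(1, n_background)
    w[background %in% gene_sets[[planted]]] <- enrich_factor
    gene_list <- sample(background, list_size, prob = w)
    list(background = background, gene_sets = gene_sets,
         gene_list = gene_list,
         truth = new_truth("planted_enrichment", seed,
                           list(term = planted, enrich_factor = enrich_factor)))
  })
}
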