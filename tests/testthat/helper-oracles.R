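# Independent oracles used to cross-check the implementation.

# Brute-force ODE right-hand side: iterate reactions one by one and
# accumulate +/- stoichiometry * flux per species, with no matrix algebra.
rhs_bruteforce <- function(model, state) {
  dx <- stats::setNames(rep(0, length(model$species)),
                        vapply(model$species, `[[`, character(1), "id"))
  for (r in model$reactions) {
    v <- mass_action_flux(r, state)
    for (s in names(r$reactants)) dx[[s]] <- dx[[s]] - r$reactants[[s]] * v
    for (s in names(r$products)) dx[[s]] <- dx[[s]] + r$products[[s]] * v
  }
  for (sp in model$species) if (sp$is_boundary) dx[[sp$id]] <- 0
  for (rl in model$rules) if (rl$kind == "assignment") dx[[rl$target]] <- 0
  dx
}

# Naive O(n^2) Benjamini-Hochberg step-up: for every p_i take the minimum of
# n * p_j / rank(p_j) over all j with p_j >= p_i, capped at 1.
bh_naive <- function(p) {
  n <- length(p)
  ranks <- vapply(p, function(pi) sum(p <= pi), numeric(1))
  vapply(seq_len(n), function(i) {
    cand <- n * p[p >= p[i]] / ranks[p >= p[i]]
    min(1, min(cand))
  }, numeric(1))
}

# Exhaustive hypergeometric upper tail P(overlap >= k) by enumerating every
# possible draw of size n from a background of size N containing K marked
# genes.
hyper_enum <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked) >= k)
  mean(hits)
}

# Toy irreversible decay model S -> P with rate k1.
decay_model <- function(k1 = 0.5, s0 = 2) {
  sig_model("decay",
            list(species("S", initial_concentration = s0), species("P")),
            list(reaction("deg", c(S = 1), c(P = 1), kf = k1)))
}

# Is vector v in the row span of the (integer) basis matrix B?
in_span <- function(v, basis_list) {
  if (length(basis_list) == 0L) return(all(v == 0))
  B <- do.call(rbind, basis_list)
  qr(B)$rank == qr(rbind(B, v))$rank
}
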