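#' Phred quality score
#'
#' Converts a base-calling error probability E into a quality score
#' `Q = -10 * log(E, base)`. The Phred standard uses base 10 (E = 0.01 gives
#' Q20); a base-2 variant is also supported via the `base` argument.
#'
#' @param error_rate Error probability(ies) in (0, 1].
#' @param base Logarithm base, 10 (default, the Phred standard) or 2.
#' @return Numeric Q score(s).
#' @export
phred_q <- function(error_rate, base = 10) {
  if (any(!is.finite(error_rate)) || any(error_rate <= 0) || any(error_rate > 1)) {
    stop("error_rate must lie in (0, 1]")
  }
  -10 * log(error_rate, base = base)
}

#' Construct a sequencing-read quality record
#'
#' @param id Read identifier.
#' @param qualities Numeric vector of per-base Phred Q scores.
#' @param fraction_N Proportion of ambiguous (N) bases, in \[0, 1\]. Defaults
#'   to 0.
#' @param has_adapter Whether adapter sequence was detected.
#' @return An object of class `read_record`.
#' @export
read_record <- function(id, qualities, fraction_N = 0, has_adapter = FALSE) {
  stopifnot(is.numeric(qualities), length(qualities) >= 1L)
  if (fraction_N < 0 || fraction_N > 1) stop("fraction_N must lie in [0, 1]")
  structure(list(id = id, qualities = as.numeric(qualities),
                 fraction_N = fraction_N, has_adapter = isTRUE(has_adapter)),
            class = "read_record")
}

#' Filter sequencing reads by quality
#'
#' Applies three independent discard rules, in order: (1) adapter
#' contamination; (2) more than `max_N_frac` ambiguous (N) bases;
#' (3) more than `max_low_q_frac` of bases with quality below
#' `low_q_threshold`. A read failing any rule is discarded and counted
#' against the first rule it fails.
#'
#' @param reads List of [read_record()]s.
#' @param max_N_frac Maximum tolerated N fraction (default 0.20).
#' @param low_q_threshold Quality threshold defining a low-quality base
#'   (default Q20).
#' @param max_low_q_frac Maximum tolerated fraction of low-quality bases
#'   (default 0.50).
#' @return List with `kept` (the surviving [read_record()]s) and `discarded`
#'   (named integer counts per rule: `adapter`, `n_bases`, `low_quality`).
#' @export
filter_reads <- function(reads, max_N_frac = 0.20, low_q_threshold = 20,
                         max_low_q_frac = 0.50) {
  stopifnot(max_N_frac >= 0, max_N_frac <= 1,
            max_low_q_frac >= 0, max_low_q_frac <= 1)
  counts <- c(adapter = 0L, n_bases = 0L, low_quality = 0L)
  kept <- list()
  for (r in reads) {
    stopifnot(inherits(r, "read_record"))
    if (r$has_adapter) {
      counts[["adapter"]] <- counts[["adapter"]] + 1L
    } else if (r$fraction_N > max_N_frac) {
      counts[["n_bases"]] <- counts[["n_bases"]] + 1L
    } else if (mean(r$qualities < low_q_threshold) > max_low_q_frac) {
      counts[["low_quality"]] <- counts[["low_quality"]] + 1L
    } else {
      kept[[length(kept) + 1L]] <- r
    }
  }
  list(kept = kept, discarded = counts)
}

#' Construct a gene-level count table
#'
#' @param counts Numeric gene x sample matrix of read counts (rownames =
#'   gene ids).
#' @param length_kb Numeric vector of exon lengths in kilobases, one per
#'   gene.
#' @param mapped_millions Numeric vector of mapped-read totals in millions,
#'   one per sample.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, length_kb, mapped_millions) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  stopifnot(length(length_kb) == nrow(counts),
            length(mapped_millions) == ncol(counts))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(length_kb <= 0)) stop("gene lengths must be positive (kb)")
  if (any(mapped_millions <= 0)) stop("mapped totals must be positive (millions)")
  structure(list(counts = counts, length_kb = as.numeric(length_kb),
                 mapped_millions = as.numeric(mapped_millions)),
            class = "count_table")
}

#' RPKM expression values
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `RPKM[g, s] = counts[g, s] / (mapped_millions[s] * length_kb[g])`.
#'
#' @param table A [count_table()].
#' @return Numeric gene x sample matrix of RPKM values.
#' @export
rpkm <- function(table) {
  stopifnot(inherits(table, "count_table"))
  sweep(table$counts / table$length_kb, 2, table$mapped_millions, "/")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (the "q-value" reported by the
#' differential-expression pipeline). A thin, validated wrapper around
#' `stats::p.adjust(method = "BH")`: input order is preserved, ties and
#' unsorted input are handled, results are capped at 1.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed genes
#'
#' Adjusts the per-gene p-values across all genes with Benjamini-Hochberg
#' and calls a gene up-regulated if `q < q_threshold` and the fold change
#' exceeds 1, down-regulated if `q < q_threshold` and the fold change is
#' below 1, and unchanged otherwise.
#'
#' @param stats_df Data frame with columns `gene_id`, `log2fc` (log2 fold
#'   change treated/untreated) and `pvalue`; one row per gene.
#' @param q_threshold Significance threshold on the adjusted q-value
#'   (default 0.01).
#' @return Data frame with columns `gene_id`, `log2fc`, `pvalue`, `qvalue`,
#'   `direction` (`"up"`, `"down"`, `"none"`).
#' @export
call_degs <- function(stats_df, q_threshold = 0.01) {
  req <- c("gene_id", "log2fc", "pvalue")
  if (!all(req %in% names(stats_df))) {
    stop("stats_df must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(stats_df$gene_id)) stop("duplicate gene ids in stats_df")
  q <- bh_adjust(stats_df$pvalue)
  sig <- q < q_threshold
  direction <- ifelse(!sig, "none",
                      ifelse(stats_df$log2fc > 0, "up",
                             ifelse(stats_df$log2fc < 0, "down", "none")))
  data.frame(gene_id = stats_df$gene_id, log2fc = stats_df$log2fc,
             pvalue = stats_df$pvalue, qvalue = q, direction = direction,
             stringsAsFactors = FALSE)
}

#' Hypergeometric gene-set enrichment
#'
#' For each term, tests over-representation of the gene list among the
#' term's members with the upper-tail hypergeometric probability
#' `P(X >= k)` (k = overlap, K = term size, n = list size, N = background
#' size), then adjusts across terms with Benjamini-Hochberg.
#'
#' @param gene_list Character vector of genes of interest (must be a subset
#'   of `background`).
#' @param gene_sets Named list: term id -> character vector of member genes
#'   (each a subset of `background`).
#' @param background Character vector: the gene universe. Defaults to the
#'   union of all annotation members and the gene list.
#' @return Data frame with columns `term`, `k`, `K`, `n`, `N`, `pvalue`,
#'   `qvalue`, ordered by increasing p-value.
#' @export
hypergeom_enrichment <- function(gene_list, gene_sets,
                                 background = union(unlist(gene_sets), gene_list)) {
  gene_list <- unique(gene_list)
  background <- unique(background)
  if (!all(gene_list %in% background)) {
    stop("gene list contains genes absent from the background: ",
         paste(utils::head(setdiff(gene_list, background), 5), collapse = ", "))
  }
  for (tm in names(gene_sets)) {
    if (!all(gene_sets[[tm]] %in% background)) {
      stop("term '", tm, "' contains genes absent from the background")
    }
  }
  N <- length(background)
  n <- length(gene_list)
  res <- lapply(names(gene_sets), function(tm) {
    members <- unique(gene_sets[[tm]])
    K <- length(members)
    k <- length(intersect(gene_list, members))
    # upper tail P(X >= k); phyper's lower.tail=FALSE gives P(X > k-1)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N, pvalue = p,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, res)
  df$qvalue <- bh_adjust(df$pvalue)
  df[order(df$pvalue, df$term), , drop = FALSE]
}

#' Read gene sets from a GMT file
#'
#' GMT: one term per line, tab-separated: term id, description, member
#' genes.
#'
#' @param path Path to a GMT file.
#' @return Named list term -> character vector of members.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) stop("malformed GMT line: ", substr(ln, 1, 60))
    sets[[parts[1]]] <- parts[-(1:2)]
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets Named list term -> members.
#' @param path Output path.
#' @param descriptions Optional named character vector of term descriptions.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  lines <- vapply(names(gene_sets), function(tm) {
    desc <- if (!is.null(descriptions) && tm %in% names(descriptions)) {
      descriptions[[tm]]
    } else "na"
    paste(c(tm, desc, gene_sets[[tm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
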