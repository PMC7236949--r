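# Pilot-data fitting: per-gene BNB fits on a paired count matrix (e.g. tumor
# vs matched normal), summarized by percentiles of the estimated baseline
# mean and dispersion. These percentiles are the natural inputs for the
# power procedure when designing a new study from pilot data.

#' Fit the BNB model to every gene of a paired count matrix
#'
#' For each gene the full BNB model (free fold ratio) is fitted to the
#' paired counts defined by `pair_map`; genes with all-zero counts or
#' non-convergent fits are excluded and counted. The estimated baseline
#' means and dispersions are summarized at the 20th, 50th and 80th
#' percentiles, the summary used to pick representative scenario parameters
#' for a power analysis.
#'
#' @param counts Matrix or data.frame of non-negative counts, genes in rows,
#'   samples in columns; a `gene_id` column (or row names) identifies genes.
#' @param pair_map `data.frame` with columns `subject`, `colA`, `colB`:
#'   the two column names holding each subject's pair of samples.
#' @param offsets Optional named per-sample log normalization offsets
#'   (e.g. log TMM-scaled library size factors). Counts are rescaled by
#'   `exp(-offset)` and rounded back to integers; the number of cells whose
#'   value changed in rounding is recorded.
#' @param baseline Which member of each pair is the baseline condition whose
#'   mean is reported as mu: `"colB"` (default, e.g. matched normal when
#'   colA is tumor) or `"colA"`.
#' @return An object of class `"pilot_summary"`: `per_gene` (a `data.frame`
#'   with `gene_id`, `mu_hat`, `gamma_hat`, `phi_hat`, `converged`),
#'   `percentiles` (`$mu` and `$phi`, each at 20/50/80), `n_excluded`,
#'   `n_rounded`.
#' @export
pilot_fit <- function(counts, pair_map, offsets = NULL,
                      baseline = c("colB", "colA")) {
  baseline <- match.arg(baseline)
  cm <- as_count_matrix(counts)
  if (!all(c("subject", "colA", "colB") %in% names(pair_map)))
    stop("'pair_map' needs columns subject, colA, colB", call. = FALSE)
  if (nrow(pair_map) < 2L)
    stop("'pair_map' must cover at least 2 subjects", call. = FALSE)
  used <- c(pair_map$colA, pair_map$colB)
  missing_cols <- setdiff(used, colnames(cm))
  if (length(missing_cols) > 0L)
    stop("pair_map columns not in the matrix: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  n_rounded <- 0L
  if (!is.null(offsets)) {
    if (is.null(names(offsets)) || !all(used %in% names(offsets)))
      stop("'offsets' must be named for every mapped sample", call. = FALSE)
    for (cn in unique(used)) {
      scaled <- cm[, cn] * exp(-offsets[[cn]])
      rounded <- round(scaled)
      n_rounded <- n_rounded + sum(rounded != cm[, cn])
      cm[, cn] <- rounded
    }
  }

  acol <- if (baseline == "colB") pair_map$colB else pair_map$colA
  bcol <- if (baseline == "colB") pair_map$colA else pair_map$colB
  xs <- cm[, acol, drop = FALSE]   # baseline condition
  ys <- cm[, bcol, drop = FALSE]

  res <- data.frame(gene_id = rownames(cm),
                    mu_hat = NA_real_, gamma_hat = NA_real_,
                    phi_hat = NA_real_, converged = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cm))) {
    if (sum(xs[i, ]) + sum(ys[i, ]) == 0) next
    fit <- tryCatch(bnb_fit(paired_counts(xs[i, ], ys[i, ])),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    res$mu_hat[i] <- fit$params$mu
    res$gamma_hat[i] <- fit$params$gamma
    res$phi_hat[i] <- fit$params$phi
    res$converged[i] <- TRUE
  }
  conv <- res[res$converged, ]
  probs <- c(0.2, 0.5, 0.8)
  pct <- list(mu = stats::quantile(conv$mu_hat, probs, names = TRUE),
              phi = stats::quantile(conv$phi_hat, probs, names = TRUE))
  structure(list(per_gene = res, percentiles = pct,
                 n_excluded = sum(!res$converged),
                 n_rounded = n_rounded),
            class = "pilot_summary")
}

as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    idcol <- which(names(counts) == "gene_id")
    if (length(idcol) == 1L) {
      rn <- as.character(counts$gene_id)
      counts <- counts[, -idcol, drop = FALSE]
    } else rn <- rownames(counts)
    counts <- as.matrix(counts)
    rownames(counts) <- rn
  }
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  if (any(counts < 0) || anyNA(counts))
    stop("counts must be non-negative and complete", call. = FALSE)
  if (any(counts != round(counts)))
    stop("counts must be integers; apply offsets for normalized data",
         call. = FALSE)
  counts
}

#' @export
print.pilot_summary <- function(x, ...) {
  n <- nrow(x$per_gene)
  cat(sprintf("Pilot BNB fits: %d genes, %d excluded (all-zero or non-convergent)\n",
              n, x$n_excluded))
  if (x$n_rounded > 0)
    cat(sprintf("  %d count cells changed by offset rounding\n", x$n_rounded))
  cat("  mu percentiles (20/50/80): ",
      paste(signif(x$percentiles$mu, 4), collapse = ", "), "\n")
  cat("  phi percentiles (20/50/80):",
      paste(signif(x$percentiles$phi, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a synthetic paired pilot count matrix
#'
#' Emulates a paired tumor/normal pilot data set: per-gene parameters
#' (mu, phi, gamma) are drawn from log-normal laws and counts simulated via
#' the BNB generator. Returns the count table (genes x 2*n_pairs), the pair
#' map and the per-gene truth, and optionally writes them as TSV.
#'
#' @param n_genes Number of genes.
#' @param n_pairs Number of subject pairs.
#' @param mu_law,phi_law,gamma_law Named lists `list(meanlog=, sdlog=)` for
#'   the log-normal laws of mu, phi and gamma. Defaults emulate a bulk
#'   RNA-Seq pilot: median mu 600 with a heavy right tail, median phi 0.2,
#'   and fold ratios concentrated near 1.
#' @param seed Integer seed.
#' @param dir Optional directory; when given, `counts.tsv`, `pair_map.tsv`
#'   and `truth.tsv` are written there.
#' @return A list with `counts` (data.frame with `gene_id` first column),
#'   `pair_map`, `truth`, and (when written) `files`.
#' @export
generate_fixture <- function(n_genes, n_pairs,
                             mu_law = list(meanlog = log(600), sdlog = 2),
                             phi_law = list(meanlog = log(0.2), sdlog = 1.5),
                             gamma_law = list(meanlog = 0, sdlog = 0.25),
                             seed = 1L, dir = NULL) {
  stopifnot(n_genes >= 0, n_pairs >= 1)
  set.seed(seed)
  gid <- if (n_genes > 0) sprintf("gene%05d", seq_len(n_genes)) else character()
  mu <- stats::rlnorm(n_genes, mu_law$meanlog, mu_law$sdlog)
  phi <- stats::rlnorm(n_genes, phi_law$meanlog, phi_law$sdlog)
  gamma <- stats::rlnorm(n_genes, gamma_law$meanlog, gamma_law$sdlog)
  tumor <- matrix(0L, n_genes, n_pairs)
  normal <- matrix(0L, n_genes, n_pairs)
  for (i in seq_len(n_genes)) {
    d <- bnb_rvs(bnb_params(mu[i], gamma[i], phi[i]), n_pairs)
    normal[i, ] <- d$x
    tumor[i, ] <- d$y
  }
  subjects <- sprintf("subj%03d", seq_len(n_pairs))
  cn <- c(paste0(subjects, "_tumor"), paste0(subjects, "_normal"))
  counts <- data.frame(gene_id = gid,
                       cbind(tumor, normal), stringsAsFactors = FALSE)
  names(counts)[-1L] <- cn
  pair_map <- data.frame(subject = subjects,
                         colA = paste0(subjects, "_tumor"),
                         colB = paste0(subjects, "_normal"),
                         stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = gid, mu = mu, phi = phi, gamma = gamma,
                      stringsAsFactors = FALSE)
  out <- list(counts = counts, pair_map = pair_map, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- file.path(dir, c("counts.tsv", "pair_map.tsv", "truth.tsv"))
    utils::write.table(counts, files[1L], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(pair_map, files[2L], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(truth, files[3L], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$files <- files
  }
  out
}
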