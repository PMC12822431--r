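## Gene-cluster occupancy classification and pangenome growth curves.

#' Default occupancy thresholds for n genomes
#'
#' Occupancy classes partition the occupancy range `[1, n]`: private (exactly
#' 1 genome), dispensable (`2` to `n-3`), softcore (`n-2` to `n-1`) and core
#' (all `n`). The softcore band generalizes the 12-13-of-14 convention used
#' for mid-sized plant pangenomes.
#'
#' @param n_genomes Number of genomes in the pangenome (>= 4 for all four
#'   classes to be non-empty).
#' @return A named list of integer `c(lo, hi)` bounds.
#' @export
occupancy_thresholds <- function(n_genomes) {
  if (n_genomes < 4)
    stop("need at least 4 genomes for the four default occupancy classes",
         call. = FALSE)
  list(private = c(1L, 1L),
       dispensable = c(2L, n_genomes - 3L),
       softcore = c(n_genomes - 2L, n_genomes - 1L),
       core = c(n_genomes, n_genomes))
}

check_thresholds <- function(thresholds, n_genomes) {
  covered <- integer(0)
  for (nm in names(thresholds)) {
    b <- thresholds[[nm]]
    if (length(b) != 2L || b[1L] > b[2L] || b[1L] < 1L || b[2L] > n_genomes)
      stop("threshold '", nm, "' out of range [1, n_genomes]", call. = FALSE)
    covered <- c(covered, seq.int(b[1L], b[2L]))
  }
  if (anyDuplicated(covered))
    stop("occupancy thresholds overlap", call. = FALSE)
  if (!setequal(covered, seq_len(n_genomes)))
    stop("occupancy thresholds do not partition [1, n_genomes]", call. = FALSE)
  invisible(TRUE)
}

#' Classify gene clusters by genome occupancy
#'
#' @param presence Logical or 0/1 matrix, clusters x genomes (rownames =
#'   cluster ids), or a data.frame coercible to one.
#' @param thresholds Named list of `c(lo, hi)` occupancy bounds that
#'   partition `[1, n_genomes]`; defaults to [occupancy_thresholds()].
#' @return A list with `labels` (data.frame: `cluster_id`, `occupancy`,
#'   `class`) and `counts` (named integer vector per class, in threshold
#'   order).
#' @examples
#' m <- matrix(rbinom(14 * 20, 1, 0.7), 20, 14)
#' rownames(m) <- paste0("clu", 1:20)
#' m[1, ] <- 1                                   # a core cluster
#' classify_occupancy(m)$counts
#' @export
classify_occupancy <- function(presence, thresholds = NULL) {
  presence <- as.matrix(presence)
  n_genomes <- ncol(presence)
  if (is.null(thresholds)) thresholds <- occupancy_thresholds(n_genomes)
  check_thresholds(thresholds, n_genomes)

  occ <- as.integer(rowSums(presence > 0))
  if (any(occ == 0))
    stop("clusters with zero occupancy are not valid pangenome members",
         call. = FALSE)
  class_of <- character(n_genomes)
  for (nm in names(thresholds)) {
    b <- thresholds[[nm]]
    class_of[seq.int(b[1L], b[2L])] <- nm
  }
  lab <- class_of[occ]
  ids <- rownames(presence)
  if (is.null(ids)) ids <- sprintf("cluster_%05d", seq_len(nrow(presence)))
  counts <- vapply(names(thresholds), function(nm) sum(lab == nm), integer(1))
  list(labels = data.frame(cluster_id = ids, occupancy = occ, class = lab,
                           stringsAsFactors = FALSE),
       counts = counts)
}

#' Pangenome growth curves by random genome sampling
#'
#' For each subset size `k` in `1..n_genomes`, draws random genome
#' combinations (each combination sampled without replacement; combinations
#' redrawn independently across repeats, the "totally random" scheme) and
#' records the pan size (clusters present in at least one member) and core
#' size (clusters present in all members).
#'
#' @param presence Clusters x genomes presence matrix.
#' @param n_subsets_per_size Combinations drawn per repeat for each size.
#' @param n_repeats Repeated sampling rounds.
#' @param seed Integer seed.
#' @return A data.frame with one row per size: `k`, `pan_mean`, `pan_q025`,
#'   `pan_q975`, `core_mean`, `core_q025`, `core_q975`, `n_samples`.
#' @export
growth_curves <- function(presence, n_subsets_per_size = 500L,
                          n_repeats = 30L, seed = 1L) {
  presence <- as.matrix(presence) > 0
  n <- ncol(presence)
  if (!nrow(presence) || !n) stop("presence matrix is empty", call. = FALSE)
  set.seed(seed)

  n_draw <- n_subsets_per_size * n_repeats
  out <- vector("list", n)
  for (k in seq_len(n)) {
    pan <- core <- integer(n_draw)
    for (i in seq_len(n_draw)) {
      members <- sample.int(n, k)
      sub <- presence[, members, drop = FALSE]
      hits <- rowSums(sub)
      pan[i] <- sum(hits > 0L)
      core[i] <- sum(hits == k)
    }
    qp <- stats::quantile(pan, c(0.025, 0.975), names = FALSE)
    qc <- stats::quantile(core, c(0.025, 0.975), names = FALSE)
    out[[k]] <- data.frame(k = k, pan_mean = mean(pan),
                           pan_q025 = qp[1L], pan_q975 = qp[2L],
                           core_mean = mean(core),
                           core_q025 = qc[1L], core_q975 = qc[2L],
                           n_samples = n_draw)
  }
  do.call(rbind, out)
}

#' Two-sided rank-sum comparison of two groups
#'
#' Thin wrapper around the Wilcoxon rank-sum test (exact for small untied
#' samples, normal approximation with tie correction otherwise), as used for
#' contrasting Ka/Ks or expression distributions between gene categories.
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @return A list: `p_value`, `median_a`, `median_b`, `statistic`, `method`.
#' @export
compare_groups <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b))
    stop("both groups must be non-empty", call. = FALSE)
  if (length(unique(c(values_a, values_b))) == 1L) {
    warning("all values tied across both groups; p set to 1")
    return(list(p_value = 1, median_a = stats::median(values_a),
                median_b = stats::median(values_b),
                statistic = NA_real_, method = "degenerate (all tied)"))
  }
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = "two.sided"))
  list(p_value = min(wt$p.value, 1), median_a = stats::median(values_a),
       median_b = stats::median(values_b),
       statistic = unname(wt$statistic), method = wt$method)
}
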