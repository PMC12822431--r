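## Haplotype-combination analysis over a small set of focal TE/SV
## presence/absence variants, with phenotype and ecotype summaries.

#' Build haplotype combinations over focal variants
#'
#' Each accession with a homozygous, non-missing call at every focal variant
#' is assigned the combination of presence (dosage 2) / absence (dosage 0)
#' states; accessions with any missing or heterozygous call are excluded and
#' counted separately. Combination frequency is the accession count over
#' classifiable accessions, and combinations with frequency strictly above
#' `min_freq` are marked retained.
#'
#' @param gm Dosage matrix restricted to the K focal variants (rows).
#' @param min_freq Retention threshold on combination frequency.
#' @return A list: `combos` (data.frame `combo` (e.g. `"P|A|P"` in row
#'   order of `gm`), `n`, `frequency`, `retained`, ordered by decreasing
#'   frequency), `assignments` (per classifiable accession: `accession`,
#'   `combo`, `n_carried`), `n_classifiable`, `n_excluded`.
#' @export
build_combos <- function(gm, min_freq = 0.05) {
  if (!nrow(gm)) stop("need at least one focal variant", call. = FALSE)
  ok <- colSums(is.na(gm)) == 0 & colSums(gm == 1L, na.rm = TRUE) == 0
  if (!any(ok))
    stop("no classifiable accessions (all have missing or heterozygous ",
         "calls at the focal variants)", call. = FALSE)
  sub <- gm[, ok, drop = FALSE]
  state <- ifelse(sub > 0, "P", "A")
  combo <- apply(state, 2L, paste, collapse = "|")
  tab <- sort(table(combo), decreasing = TRUE)
  combos <- data.frame(combo = names(tab), n = as.integer(tab),
                       frequency = as.integer(tab) / sum(ok),
                       stringsAsFactors = FALSE)
  combos$retained <- combos$frequency > min_freq
  assignments <- data.frame(accession = colnames(sub), combo = combo,
                            n_carried = as.integer(colSums(sub > 0)),
                            stringsAsFactors = FALSE)
  list(combos = combos, assignments = assignments,
       n_classifiable = sum(ok), n_excluded = sum(!ok))
}

#' Summarize phenotype and ecotype composition per haplotype combination
#'
#' Reports the trait mean and SD and the ecotype composition of each
#' combination, plus carried-variation counts per ecotype: for each ecotype
#' and each number of carried focal variants, the accession count and its
#' percentage of that ecotype. Percentages are truncated to integers
#' (`floor`), the convention behind statements like "104 (78%) of 132
#' spring accessions carried two variations".
#'
#' @param combos Output of [build_combos()].
#' @param phenotype Data.frame with `accession`, the trait column and an
#'   `ecotype` column.
#' @param trait Name of the trait column in `phenotype`.
#' @return A list: `per_combo` (combo, n, frequency, retained, trait
#'   mean/sd, one `eco_<label>` count column per ecotype) and `carriage`
#'   (`ecotype`, `n_carried`, `n`, `pct` (truncated), `n_at_least`,
#'   `pct_at_least`).
#' @export
combo_summary <- function(combos, phenotype, trait) {
  stopifnot(trait %in% names(phenotype), "ecotype" %in% names(phenotype))
  a <- merge(combos$assignments, phenotype, by = "accession")
  eco_levels <- sort(unique(phenotype$ecotype))

  per_combo <- combos$combos
  per_combo$trait_mean <- NA_real_
  per_combo$trait_sd <- NA_real_
  for (e in eco_levels) per_combo[[paste0("eco_", e)]] <- 0L
  for (i in seq_len(nrow(per_combo))) {
    x <- a[a$combo == per_combo$combo[i], , drop = FALSE]
    if (nrow(x)) {
      per_combo$trait_mean[i] <- mean(x[[trait]], na.rm = TRUE)
      per_combo$trait_sd[i] <- if (sum(!is.na(x[[trait]])) > 1)
        stats::sd(x[[trait]], na.rm = TRUE) else NA_real_
      for (e in eco_levels)
        per_combo[[paste0("eco_", e)]][i] <- sum(x$ecotype == e)
    }
    if (all(is.na(x[[trait]]))) per_combo$trait_mean[i] <- NA_real_
  }

  carriage <- do.call(rbind, lapply(eco_levels, function(e) {
    x <- a[a$ecotype == e, , drop = FALSE]
    n_eco <- nrow(x)
    ks <- 0:max(a$n_carried)
    data.frame(ecotype = e, n_carried = ks,
               n = vapply(ks, function(k) sum(x$n_carried == k), integer(1)),
               pct = vapply(ks, function(k)
                 truncated_pct(sum(x$n_carried == k), n_eco), numeric(1)),
               n_at_least = vapply(ks, function(k)
                 sum(x$n_carried >= k), integer(1)),
               pct_at_least = vapply(ks, function(k)
                 truncated_pct(sum(x$n_carried >= k), n_eco), numeric(1)),
               stringsAsFactors = FALSE)
  }))
  list(per_combo = per_combo, carriage = carriage)
}

#' Integer-truncated percentage
#'
#' `floor(100 * k / n)`; e.g. 104 of 132 gives 78.
#'
#' @param k,n Counts (`n > 0`).
#' @return Truncated integer percentage.
#' @examples
#' truncated_pct(104, 132)
#' @export
truncated_pct <- function(k, n) {
  if (n <= 0) return(NA_real_)
  floor(100 * k / n)
}
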