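#' Total admixture proportion attributed to stocking sources
#'
#' Several stocked lakes received fish from two hatchery source populations,
#' so their admixture analyses carry one cluster per source. The stocking
#' proportion used for classification is the sum of Q over all source
#' clusters, i.e. Q_source = 1 - Q_local.
#'
#' @param q named numeric vector of cluster proportions summing to 1
#' @param source_clusters names of the clusters designated as stocking
#'   sources (non-empty subset of `names(q)`)
#' @return the summed source proportion
#' @export
q_source <- function(q, source_clusters) {
  if (length(source_clusters) == 0) {
    stop("q_source: source_clusters must be non-empty", call. = FALSE)
  }
  unknown <- setdiff(source_clusters, names(q))
  if (length(unknown) > 0) {
    stop(sprintf("q_source: unknown cluster label(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (abs(sum(q) - 1) > 1e-6) {
    stop("q_source: cluster proportions must sum to 1", call. = FALSE)
  }
  sum(q[source_clusters])
}

#' Classify genetic origin from a stocking-source admixture proportion
#'
#' Threshold rule on the source admixture proportion and its bootstrap SE:
#' a fish is classified as stocked when q_src + se >= q_high, local when
#' q_src + se <= q_low, and hybrid otherwise. Both boundary comparisons are
#' inclusive. The printed rule adds the SE on both sides, which is
#' asymmetric for the local boundary; `symmetric_se = TRUE` switches the
#' local rule to q_src - se <= q_low, the variant in which the SE widens the
#' hybrid band symmetrically.
#'
#' @param q_src source admixture proportion(s) in [0, 1]
#' @param se bootstrap SE(s) of Q (>= 0), recycled against `q_src`
#' @param q_low,q_high classification thresholds (defaults 0.10 and 0.90)
#' @param symmetric_se use q_src - se for the local boundary
#' @return factor with ordered levels local < hybrid < stocked
#' @export
classify_origin <- function(q_src, se = 0, q_low = 0.10, q_high = 0.90,
                            symmetric_se = FALSE) {
  if (any(q_src < 0 | q_src > 1)) {
    stop("classify_origin: q_src must lie in [0, 1]", call. = FALSE)
  }
  if (any(se < 0)) stop("classify_origin: se must be >= 0", call. = FALSE)
  if (!(q_low > 0 && q_high < 1 && q_low < q_high)) {
    stop("classify_origin: thresholds must satisfy 0 < q_low < q_high < 1",
         call. = FALSE)
  }
  se <- rep_len(se, length(q_src))
  local_side <- if (symmetric_se) q_src - se else q_src + se
  lab <- ifelse(q_src + se >= q_high, "stocked",
                ifelse(local_side <= q_low, "local", "hybrid"))
  factor(lab, levels = c("local", "hybrid", "stocked"))
}

#' Per-lake origin composition
#'
#' Counts fish of each genetic origin per lake and expresses them as
#' within-lake percentages rounded half-up to one decimal.
#'
#' @param origin vector of origin labels (local/hybrid/stocked)
#' @param lake parallel vector of lake names
#' @return data.frame with one row per lake: n, n_local, n_hybrid,
#'   n_stocked, pct_local, pct_hybrid, pct_stocked
#' @export
summarize_origins <- function(origin, lake) {
  if (length(origin) == 0) {
    warning("summarize_origins: no fish supplied; empty summary")
    return(data.frame(lake = character(0), n = integer(0),
                      n_local = integer(0), n_hybrid = integer(0),
                      n_stocked = integer(0), pct_local = numeric(0),
                      pct_hybrid = numeric(0), pct_stocked = numeric(0)))
  }
  origin <- factor(as.character(origin), levels = c("local", "hybrid", "stocked"))
  tab <- table(lake = lake, origin = origin)
  out <- data.frame(lake = rownames(tab), n = as.integer(rowSums(tab)),
                    n_local = as.integer(tab[, "local"]),
                    n_hybrid = as.integer(tab[, "hybrid"]),
                    n_stocked = as.integer(tab[, "stocked"]),
                    stringsAsFactors = FALSE)
  for (o in c("local", "hybrid", "stocked")) {
    out[[paste0("pct_", o)]] <- round_half_up(100 * out[[paste0("n_", o)]] / out$n, 1)
  }
  rownames(out) <- NULL
  out
}
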