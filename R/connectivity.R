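## Connectivity-map scoring: the signed Kolmogorov-Smirnov tag enrichment
## statistic on ranked drug-response signatures, up/down connectivity scores
## with batch rescaling, per-drug aggregation, and anchor-oriented candidate
## selection.

## Core KS statistic over the ascending tag positions V (length t) in a ranked
## list of n: a = max_j[j/t - V(j)/n], b = max_j[V(j)/n - (j-1)/t];
## ES = a if a > b else -b. Positive = tags concentrate at the top.
ks_es_positions <- function(positions, n) {
  t <- length(positions)
  v <- sort(positions)
  j <- seq_len(t)
  a <- max(j / t - v / n)
  b <- max(v / n - (j - 1) / t)
  if (a > b) a else -b
}

ranking_from <- function(signature) {
  if (is.character(signature)) return(signature)
  if (is.data.frame(signature)) {
    if (!"gene" %in% names(signature)) {
      abort("A signature data frame must have a `gene` column (in rank order).")
    }
    return(as.character(signature$gene))
  }
  abort("`signature` must be a character ranking or a data frame with a `gene` column.")
}

#' KS tag enrichment on a ranked signature
#'
#' Computes the signed Kolmogorov-Smirnov enrichment statistic of a tag gene
#' set within a ranked expression signature (position 1 = most up-regulated).
#' Positive values mean the tags concentrate at the top of the list, negative
#' at the bottom; the statistic always lies in \[-1, 1\].
#'
#' @param signature A character vector giving the full gene ranking (a strict
#'   permutation of the universe), or a data frame with a `gene` column in
#'   rank order.
#' @param tags Non-empty character vector of tag genes.
#' @param skip_missing If `TRUE`, tags absent from the universe are dropped
#'   with a warning instead of raising an error. The default errors, so that
#'   symbol-harmonization bugs surface instead of silently shrinking the tag
#'   set.
#' @return A single number in \[-1, 1\].
#' @examples
#' sig <- paste0("G", 1:10)
#' ks_enrichment(sig, c("G1", "G2"))   #  0.8
#' ks_enrichment(sig, c("G9", "G10"))  # -0.9
#' @export
ks_enrichment <- function(signature, tags, skip_missing = FALSE) {
  ranking <- ranking_from(signature)
  n <- length(ranking)
  if (n < 2L) abort("The signature universe must contain at least 2 genes.")
  if (anyDuplicated(ranking)) {
    abort("The signature ranking must be a strict permutation (no duplicates).")
  }
  if (length(tags) == 0L) abort("`tags` must contain at least one gene.")
  pos <- match(tags, ranking)
  if (anyNA(pos)) {
    missing <- tags[is.na(pos)]
    if (!skip_missing) {
      abort(paste0("Tag gene(s) not in the signature universe: ",
                   paste(missing, collapse = ", ")))
    }
    warn(paste0("Dropping tag gene(s) not in the signature universe: ",
                paste(missing, collapse = ", ")))
    pos <- pos[!is.na(pos)]
    if (!length(pos)) abort("No tag genes left after dropping missing ones.")
  }
  if (anyDuplicated(pos)) abort("`tags` must not contain duplicates.")
  ks_es_positions(pos, n)
}

## Raw (unscaled) connectivity of one instance: ES of the up- and down-tags,
## zeroed when both sides agree in sign; a missing side contributes 0.
raw_connectivity <- function(ranking, up, down, skip_missing = FALSE) {
  es_up <- if (length(up)) ks_enrichment(ranking, up, skip_missing) else 0
  es_down <- if (length(down)) ks_enrichment(ranking, down, skip_missing) else 0
  raw <- if (length(up) && length(down) && sign(es_up) == sign(es_down)) {
    0
  } else {
    es_up - es_down
  }
  list(es_up = es_up, es_down = es_down, raw = raw)
}

## Batch rescaling: positive raws divided by the max positive raw, negative
## raws by |min negative raw|, so the extremes map to exactly +1 / -1.
scale_scores <- function(raw) {
  out <- raw
  pos <- raw > 0
  neg <- raw < 0
  if (any(pos)) out[pos] <- raw[pos] / max(raw[pos])
  if (any(neg)) out[neg] <- raw[neg] / abs(min(raw[neg]))
  out
}

#' Connectivity scores of ranked signatures against an up/down tag query
#'
#' For every instance (one drug treatment on one cell line), computes the KS
#' enrichment of the up- and down-tag sets, combines them into a raw
#' connectivity (zero when the two sides agree in sign — the signature does
#' not discriminate the query), and rescales the raw scores across the
#' instance collection so the extremes map to exactly +1 and -1.
#'
#' @param signatures Tibble with columns `instance_id`, `drug`, `cell_line`
#'   and a `ranking` list-column (each element a strict permutation of the
#'   gene universe), e.g. from [read_signatures()].
#' @param up,down Character vectors of up-/down-regulated query genes; they
#'   must be disjoint and at least one must be non-empty. Either may be empty,
#'   in which case the score reduces to the contribution of the other side.
#' @param skip_missing Passed to [ks_enrichment()].
#' @return The input tibble (minus `ranking`) with `es_up`, `es_down`, `raw`
#'   and `score` columns.
#' @export
connectivity_scores <- function(signatures, up, down = character(),
                                skip_missing = FALSE) {
  stopifnot(is.data.frame(signatures),
            all(c("instance_id", "drug", "ranking") %in% names(signatures)))
  if (length(up) == 0L && length(down) == 0L) {
    abort("At least one of `up` and `down` must be non-empty.")
  }
  if (length(intersect(up, down))) {
    abort(paste0("Up and down tag sets overlap: ",
                 paste(intersect(up, down), collapse = ", ")))
  }
  res <- map(signatures$ranking, raw_connectivity, up = up, down = down,
             skip_missing = skip_missing)
  out <- signatures |>
    select(-"ranking") |>
    mutate(es_up = map_dbl(res, "es_up"),
           es_down = map_dbl(res, "es_down"),
           raw = map_dbl(res, "raw"))
  out$score <- scale_scores(out$raw)
  out
}

#' Aggregate instance scores to per-drug connectivity results
#'
#' The drug-level `mean` is the arithmetic mean of its instances' scores. The
#' drug-level `enrichment` is the KS statistic of the drug's instance
#' positions within all instances ordered by descending score (ties broken by
#' instance id for determinism): a drug whose instances sit at the top of the
#' score ordering gets a positive enrichment, consistent with the sign of its
#' mean.
#'
#' @param instance_scores Output of [connectivity_scores()].
#' @return A `connectivity_results` tibble (`drug`, `mean`, `enrichment`,
#'   `n_instances`), ordered by decreasing mean.
#' @export
aggregate_drugs <- function(instance_scores) {
  stopifnot(all(c("instance_id", "drug", "score") %in% names(instance_scores)))
  if (nrow(instance_scores) == 0L) {
    abort("No instances to aggregate.")
  }
  ordered <- instance_scores |>
    arrange(desc(.data$score), .data$instance_id) |>
    mutate(position = dplyr::row_number())
  n <- nrow(ordered)
  out <- ordered |>
    group_by(.data$drug) |>
    summarise(mean = mean(.data$score),
              enrichment = ks_es_positions(.data$position, n),
              n_instances = dplyr::n(),
              .groups = "drop") |>
    arrange(desc(.data$mean), .data$drug)
  class(out) <- c("connectivity_results", class(out))
  out
}

#' Select final candidates by anchor concordance
#'
#' Retains a drug when the sign of its mean connectivity agrees with the mean
#' of the positive anchor drugs (known active compounds, e.g. paclitaxel and
#' vinblastine), disagrees with the mean of the negative anchors (e.g.
#' selegiline), and its magnitude reaches `min_abs_mean`. Drugs requested via
#' `drugs` but absent from the signature panel are reported with decision
#' `NOT_IN_CMAP`. Anchor drugs themselves are not returned as candidates.
#'
#' @param results A `connectivity_results` tibble from [aggregate_drugs()].
#' @param anchors_pos Non-empty character vector of positive anchor drugs;
#'   all must be present in `results`.
#' @param anchors_neg Optional negative anchor drugs; must also be present,
#'   and must disagree in sign with the positive anchors.
#' @param min_abs_mean Minimum |mean| to retain (default 0: sign agreement
#'   only — the selection criterion is a correlation sign, not a magnitude).
#' @param drugs Optional character vector restricting the candidates scored
#'   (e.g. the cascade survivors); members missing from `results` are returned
#'   as `NOT_IN_CMAP`.
#' @return Tibble (`drug`, `mean`, `enrichment`, `n_instances`, `decision`)
#'   with decision in {`RETAINED`, `REJECTED`, `NOT_IN_CMAP`}, ordered by
#'   decision, decreasing |mean|, then drug — invariant to the input order.
#' @export
select_candidates <- function(results, anchors_pos, anchors_neg = character(),
                              min_abs_mean = 0, drugs = NULL) {
  if (length(anchors_pos) == 0L) abort("`anchors_pos` must not be empty.")
  missing_anchor <- setdiff(c(anchors_pos, anchors_neg), results$drug)
  if (length(missing_anchor)) {
    abort(paste0("Anchor drug(s) absent from results: ",
                 paste(missing_anchor, collapse = ", ")))
  }
  pos_mean <- mean(results$mean[results$drug %in% anchors_pos])
  neg_mean <- if (length(anchors_neg)) {
    mean(results$mean[results$drug %in% anchors_neg])
  } else {
    NA_real_
  }
  if (length(anchors_neg) && sign(pos_mean) == sign(neg_mean)) {
    abort(paste0("Conflicting anchors: positive (", signif(pos_mean, 3),
                 ") and negative (", signif(neg_mean, 3),
                 ") anchors agree in sign; selection refused."))
  }
  cand <- results |>
    filter(!.data$drug %in% c(anchors_pos, anchors_neg))
  if (!is.null(drugs)) {
    cand <- filter(cand, .data$drug %in% drugs)
    absent <- setdiff(drugs, results$drug)
  } else {
    absent <- character()
  }
  cand <- cand |>
    mutate(decision = ifelse(
      sign(.data$mean) == sign(pos_mean) &
        (!length(anchors_neg) | sign(.data$mean) != sign(neg_mean)) &
        abs(.data$mean) >= min_abs_mean,
      "RETAINED", "REJECTED"))
  out <- bind_rows(
    cand,
    tibble(drug = sort_cx(absent), mean = NA_real_, enrichment = NA_real_,
           n_instances = 0L, decision = rep("NOT_IN_CMAP", length(absent)))
  )
  out |>
    mutate(decision = factor(.data$decision,
                             levels = c("RETAINED", "REJECTED", "NOT_IN_CMAP"))) |>
    arrange(.data$decision, desc(abs(.data$mean)), .data$drug) |>
    mutate(decision = as.character(.data$decision))
}
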