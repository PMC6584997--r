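## The drug-candidate cascade: map the unified gene set onto approved
## drug-target records, drop drugs already indicated for melanoma, then keep
## only drugs whose annotated targets are concordant (or neutral) with the
## gene's pathogenic direction. Every stage appends to an audit trace and a
## stage-count table carried on the `drug_cascade` object.

new_cascade <- function(candidates, trace, counts, trial_overlap = NA_integer_) {
  structure(list(candidates = candidates, trace = trace, counts = counts,
                 trial_overlap = trial_overlap),
            class = "drug_cascade")
}

stage_count_row <- function(stage, candidates) {
  tibble(stage = stage,
         drugs = n_distinct(candidates$drug),
         targets = n_distinct(candidates$target))
}

#' Map the unified gene set onto drug-target records
#'
#' Keeps drug-target links whose target lies in the unified melanoma gene set
#' and whose drug belongs to an allowed approval group (by default approved
#' drugs only; experimental, illicit, withdrawn, investigational and
#' nutraceutical compounds are dropped). Each retained drug's target list is
#' restricted to in-set targets.
#'
#' @param drug_targets Tibble from [parse_drug_targets()].
#' @param gene_set Character vector of harmonized symbols, e.g. from
#'   [unified_gene_set()].
#' @param groups_allowed Drug approval groups to retain.
#' @return A `drug_cascade` object holding the candidate (drug, target) rows,
#'   the per-drug audit trace, and the stage-count table. Use [tidy()] for the
#'   candidate rows and [glance()] for the counts.
#' @export
map_drugs <- function(drug_targets, gene_set, groups_allowed = "APPROVED") {
  groups_allowed <- str_to_upper(groups_allowed)
  bad <- setdiff(groups_allowed, DRUG_GROUPS)
  if (length(bad)) abort(paste0("Unknown drug group(s): ", paste(bad, collapse = ", ")))
  gene_set <- harmonize_genes(gene_set)
  cand <- drug_targets |>
    filter(.data$group %in% groups_allowed, .data$target %in% gene_set) |>
    arrange(.data$drug, .data$target)
  all_drugs <- sort_cx(unique(drug_targets$drug))
  in_group <- drug_targets |>
    filter(.data$group %in% groups_allowed) |>
    pull(.data$drug) |>
    unique()
  kept <- unique(cand$drug)
  trace <- tibble(
    drug = all_drugs,
    stage = "MAP",
    decision = ifelse(all_drugs %in% kept, "RETAINED", "REJECTED"),
    reason = dplyr::case_when(
      all_drugs %in% kept ~ "target in unified gene set",
      !all_drugs %in% in_group ~ "GROUP_EXCLUDED",
      TRUE ~ "NO_TARGET_IN_SET"
    )
  )
  new_cascade(cand, trace, stage_count_row("map", cand))
}

#' Exclude drugs with a known melanoma indication
#'
#' Removes candidates whose drug name appears in the trial list, matching
#' names case- and punctuation-insensitively (trial registries carry no
#' accession ids, so the join is name-level).
#'
#' @param cascade A `drug_cascade` from [map_drugs()].
#' @param trials Tibble from [parse_trials()].
#' @return The updated `drug_cascade`; the number of overlapping drugs is
#'   available as `$trial_overlap` and in [glance()].
#' @export
exclude_known <- function(cascade, trials) {
  stopifnot(inherits(cascade, "drug_cascade"))
  trial_norm <- unique(normalize_drug_name(trials$drug))
  cand <- cascade$candidates
  is_known <- normalize_drug_name(cand$drug) %in% trial_norm
  overlap_drugs <- unique(cand$drug[is_known])
  retained <- cand[!is_known, , drop = FALSE]
  drugs_in <- unique(cand$drug)
  trace <- tibble(
    drug = sort_cx(drugs_in),
    stage = "INDICATION_EXCLUSION",
    decision = ifelse(sort_cx(drugs_in) %in% overlap_drugs, "REJECTED", "RETAINED"),
    reason = ifelse(sort_cx(drugs_in) %in% overlap_drugs,
                    "known melanoma indication", "no known melanoma indication")
  )
  new_cascade(retained,
              bind_rows(cascade$trace, trace),
              bind_rows(cascade$counts, stage_count_row("exclude", retained)),
              trial_overlap = length(overlap_drugs))
}

#' Pathogenesis/action concordance verdicts
#'
#' Scores a drug action mode against the target's pathogenic direction. A
#' gain-of-function (GOF) disease gene wants a suppressing drug
#' (inhibitor/antagonist/blocker); a loss-of-function (LOF) gene wants an
#' enhancing one (agonist/inducer/activator). Substrate, binder and unknown
#' actions carry no direction and are neutral; the remaining combinations are
#' discordant. For a single action the strict and lenient policies agree; the
#' lenient policy only differs at the target level (see [pathogenesis_filter()]),
#' where a discordant verdict is downgraded to neutral when the target also
#' carries a neutral action.
#'
#' @param direction `"GOF"` or `"LOF"` (vectorized).
#' @param action A drug action mode (vectorized, recycled against `direction`).
#' @param policy `"strict"` (default) or `"lenient"`.
#' @return Character vector of verdicts in
#'   {`CONCORDANT`, `NEUTRAL`, `DISCORDANT`}.
#' @examples
#' concordance("GOF", "INHIBITOR")
#' concordance("LOF", c("SUBSTRATE", "INHIBITOR"))
#' @export
concordance <- function(direction, action, policy = c("strict", "lenient")) {
  policy <- match.arg(policy)
  direction <- str_to_upper(direction)
  action <- str_to_upper(action)
  bad_d <- setdiff(unique(direction), PATHOGENESIS_DIRECTIONS)
  if (length(bad_d)) abort(paste0("Unknown direction: ", paste(bad_d, collapse = ", ")))
  bad_a <- setdiff(unique(action), DRUG_ACTIONS)
  if (length(bad_a)) abort(paste0("Unknown action: ", paste(bad_a, collapse = ", ")))
  n <- max(length(direction), length(action))
  direction <- rep_len(direction, n)
  action <- rep_len(action, n)
  suppressing <- c("INHIBITOR", "ANTAGONIST", "BLOCKER")
  enhancing <- c("AGONIST", "INDUCER", "ACTIVATOR")
  neutral <- c("SUBSTRATE", "BINDER", "UNKNOWN")
  dplyr::case_when(
    action %in% neutral ~ "NEUTRAL",
    direction == "GOF" & action %in% suppressing ~ "CONCORDANT",
    direction == "LOF" & action %in% enhancing ~ "CONCORDANT",
    TRUE ~ "DISCORDANT"
  )
}

## Target-level verdict over an action set. STRICT: any concordant action wins,
## otherwise any discordant action condemns, otherwise neutral. LENIENT: a
## discordant verdict is downgraded to neutral when a neutral action co-occurs.
target_verdict <- function(direction, actions, policy = "strict") {
  v <- concordance(rep(direction, length(actions)), actions, policy)
  if (any(v == "CONCORDANT")) return("CONCORDANT")
  if (any(v == "DISCORDANT")) {
    if (policy == "lenient" && any(v == "NEUTRAL")) return("NEUTRAL")
    return("DISCORDANT")
  }
  "NEUTRAL"
}

#' Filter candidates by pathogenesis/action concordance
#'
#' Joins each candidate target against its GOF/LOF annotation and keeps a drug
#' when at least one annotated target scores concordant or neutral. Targets
#' without an annotation are dropped from consideration (drugs are judged on
#' annotated targets only); a drug left with no annotated target is rejected
#' with reason `NO_ANNOTATION`.
#'
#' @param cascade A `drug_cascade`.
#' @param annotations Tibble from [parse_pathogenesis()] (conflict-free).
#' @param policy `"strict"` or `"lenient"`, see [concordance()].
#' @return The updated `drug_cascade`; retained candidate rows keep only the
#'   annotated, non-discordant targets and gain `direction` and `verdict`
#'   columns.
#' @export
pathogenesis_filter <- function(cascade, annotations, policy = c("strict", "lenient")) {
  stopifnot(inherits(cascade, "drug_cascade"))
  policy <- match.arg(policy)
  conflict <- annotations |>
    distinct(.data$target, .data$direction) |>
    count(.data$target) |>
    filter(.data$n > 1L)
  if (nrow(conflict)) {
    abort(paste0("Conflicting GOF/LOF annotations for target(s): ",
                 paste(sort_cx(conflict$target), collapse = ", ")))
  }
  cand <- cascade$candidates |>
    inner_join(distinct(annotations, .data$target, .data$direction),
               by = "target") |>
    mutate(verdict = map2_chr(.data$direction, .data$actions, target_verdict,
                              policy = policy))
  verdict_by_drug <- cand |>
    group_by(.data$drug) |>
    summarise(keep = any(.data$verdict != "DISCORDANT"), .groups = "drop")
  kept_drugs <- verdict_by_drug$drug[verdict_by_drug$keep]
  retained <- cand |>
    filter(.data$drug %in% kept_drugs, .data$verdict != "DISCORDANT")
  drugs_in <- sort_cx(unique(cascade$candidates$drug))
  reason <- dplyr::case_when(
    drugs_in %in% kept_drugs ~ "concordant or neutral annotated target",
    drugs_in %in% verdict_by_drug$drug ~ "DISCORDANT",
    TRUE ~ "NO_ANNOTATION"
  )
  trace <- tibble(drug = drugs_in, stage = "PATHOGENESIS",
                  decision = ifelse(drugs_in %in% kept_drugs, "RETAINED", "REJECTED"),
                  reason = reason)
  new_cascade(retained,
              bind_rows(cascade$trace, trace),
              bind_rows(cascade$counts, stage_count_row("pathofilter", retained)),
              trial_overlap = cascade$trial_overlap)
}

#' @method tidy drug_cascade
#' @export
tidy.drug_cascade <- function(x, ...) x$candidates

#' @method glance drug_cascade
#' @export
glance.drug_cascade <- function(x, ...) {
  wide <- x$counts |>
    tidyr::pivot_wider(names_from = "stage", values_from = c("drugs", "targets"))
  wide$trial_overlap <- x$trial_overlap
  wide
}

#' Stage-by-stage cascade counts
#'
#' @param cascade A `drug_cascade`.
#' @return Tibble (`stage`, `drugs`, `targets`), one row per completed stage.
#' @export
cascade_counts <- function(cascade) cascade$counts

#' Per-drug audit trace of the cascade
#'
#' @param cascade A `drug_cascade`.
#' @param path Optional TSV path to write the trace to.
#' @return The trace tibble (`drug`, `stage`, `decision`, `reason`).
#' @export
cascade_trace <- function(cascade, path = NULL) {
  if (!is.null(path)) readr::write_tsv(cascade$trace, path)
  cascade$trace
}

#' @export
print.drug_cascade <- function(x, ...) {
  cat("<drug_cascade>\n")
  print(x$counts)
  if (!is.na(x$trial_overlap)) cat("trial overlap:", x$trial_overlap, "drugs\n")
  invisible(x)
}
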