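test_that("KS enrichment matches hand-evaluated cases", {
  sig <- paste0("G", 1:10)
  # tags at the extreme top: a = max(0.4, 0.8) beats b = 0.1
  expect_equal(ks_enrichment(sig, c("G1", "G2")), 0.8)
  # tags at the extreme bottom: b = 0.9 wins
  expect_equal(ks_enrichment(sig, c("G9", "G10")), -0.9)
  # all genes tagged: a = 0, b = 1/n, so ES = -1/n (oracle-confirmed)
  expect_equal(ks_enrichment(sig, sig), ks_oracle(1:10, 10))
  expect_equal(ks_enrichment(sig, sig), -0.1)
})

test_that("KS enrichment equals the brute-force oracle exactly on random cases", {
  set.seed(2026)
  for (i in 1:1000) {
    n <- sample(2:50, 1)
    t <- sample(1:n, 1)
    sig <- sample(sprintf("g%03d", 1:n))
    tags <- sample(sig, t)
    es <- ks_enrichment(sig, tags)
    cmp <- ks_oracle_ab(match(tags, sig), n)
    expect_identical(es, cmp$es)
    expect_true(abs(es) <= 1)
    # reversal: exact agreement with the oracle on the reversed ranking, and
    # negation up to the 1/n rank step when the statistic is sign-definite
    # (the discrete formula is not exactly antisymmetric)
    es_rev <- ks_enrichment(rev(sig), tags)
    expect_identical(es_rev, ks_oracle(n + 1 - match(tags, sig), n))
    if (abs(cmp$a - cmp$b) > 2 / n + 1e-9) {
      expect_lte(abs(es_rev + es), 1 / n + 1e-12)
    }
  }
})

test_that("moving a tag toward the top never decreases the enrichment", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    sig <- sprintf("g%02d", 1:n)
    tags <- sample(sig, sample(1:(n - 1), 1))
    pos <- sort(match(tags, sig))
    movable <- pos[pos > 1 & !(pos - 1) %in% pos]
    if (!length(movable)) next
    p <- movable[sample.int(length(movable), 1)]
    swapped <- sig
    swapped[c(p - 1, p)] <- swapped[c(p, p - 1)]
    expect_gte(ks_enrichment(swapped, tags), ks_enrichment(sig, tags))
  }
})

test_that("tags outside the universe are an error unless skipping is requested", {
  sig <- paste0("G", 1:10)
  expect_error(ks_enrichment(sig, c("G1", "NOPE")), "NOPE")
  expect_warning(es <- ks_enrichment(sig, c("G1", "NOPE"), skip_missing = TRUE),
                 "NOPE")
  expect_equal(es, ks_enrichment(sig, "G1"))
  expect_error(ks_enrichment(sig, character()), "at least one")
})

test_that("connectivity scoring applies the same-sign rule and batch rescaling", {
  universe <- sprintf("g%02d", 1:20)
  up <- c("g01", "g02")
  down <- c("g19", "g20")
  perfect <- universe                          # up at top, down at bottom
  reversed <- c(down, universe[3:18], up)      # the opposite response
  panel <- signature_panel(list(perfect, reversed, sample(universe)),
                           c("hit", "anti", "noise"))
  scores <- connectivity_scores(panel, up, down)
  # extremal raw scores map to exactly +/-1
  expect_equal(scores$score[scores$drug == "hit"], 1)
  expect_equal(scores$score[scores$drug == "anti"], -1)
  expect_true(all(abs(scores$score) <= 1))

  # same-sign instances are zeroed: both tag sets at the top
  both_top <- c("g01", "g19", "g02", "g20", universe[c(3:18)])
  z <- connectivity_scores(signature_panel(list(both_top), "flat"), up, down)
  expect_gt(z$es_up, 0)
  expect_gt(z$es_down, 0)
  expect_equal(z$raw, 0)

  # single-sided query: down set empty, up-tags at the bottom -> negative
  one_sided <- connectivity_scores(
    signature_panel(list(c(universe[3:20], up)), "lowup"), up, character())
  expect_lt(one_sided$score, 0)

  # both sides empty or overlapping tags are argument errors
  expect_error(connectivity_scores(panel, character(), character()), "non-empty")
  expect_error(connectivity_scores(panel, up, up), "overlap")
})

test_that("drug aggregation averages instances and ranks drugs by KS position", {
  universe <- sprintf("g%02d", 1:20)
  up <- c("g01", "g02")
  top_rank <- universe
  bottom_rank <- c(universe[3:20], up)
  panel <- signature_panel(
    list(top_rank, top_rank, bottom_rank, bottom_rank, sample(universe)),
    c("good", "good", "bad", "bad", "meh")
  )
  res <- aggregate_drugs(connectivity_scores(panel, up))
  expect_s3_class(res, "connectivity_results")
  good <- res[res$drug == "good", ]
  expect_equal(good$n_instances, 2L)
  expect_equal(good$mean, 1)
  # instances of "good" occupy the top of the score ordering
  expect_gt(good$enrichment, 0)
  expect_equal(good$enrichment, ks_oracle(c(1, 2), 5))
  expect_lt(res$enrichment[res$drug == "bad"], 0)

  # single instance: mean is the instance score
  single <- aggregate_drugs(connectivity_scores(
    signature_panel(list(top_rank), "solo"), up))
  expect_equal(single$mean, 1)

  # opposite instances cancel
  pair <- aggregate_drugs(connectivity_scores(
    signature_panel(list(top_rank, bottom_rank), c("mix", "mix")), up))
  expect_equal(pair$mean, 0)
})

test_that("anchor-based selection retains sign-concordant drugs and flags missing ones", {
  res <- tibble::tibble(
    drug = c("pos_anchor", "neg_anchor", "a", "b", "c"),
    mean = c(0.6, -0.4, 0.3, -0.2, 0.05),
    enrichment = c(0.5, -0.3, 0.2, -0.1, 0.01),
    n_instances = 2L
  )
  sel <- select_candidates(res, "pos_anchor", "neg_anchor", min_abs_mean = 0.1,
                           drugs = c("a", "b", "c", "ghost"))
  expect_equal(sel$decision[sel$drug == "a"], "RETAINED")
  expect_equal(sel$decision[sel$drug == "b"], "REJECTED")   # wrong sign
  expect_equal(sel$decision[sel$drug == "c"], "REJECTED")   # below threshold
  expect_equal(sel$decision[sel$drug == "ghost"], "NOT_IN_CMAP")
  expect_false(any(c("pos_anchor", "neg_anchor") %in% sel$drug))

  # output is invariant to input ordering
  sel2 <- select_candidates(res[sample(nrow(res)), ], "pos_anchor", "neg_anchor",
                            min_abs_mean = 0.1, drugs = c("a", "b", "c", "ghost"))
  expect_equal(sel, sel2)

  # argument errors: empty/missing anchors, agreeing anchor signs
  expect_error(select_candidates(res, character()), "anchors_pos")
  expect_error(select_candidates(res, "absent"), "absent")
  agree <- dplyr::mutate(res, mean = abs(mean))
  expect_error(select_candidates(agree, "pos_anchor", "neg_anchor"),
               "Conflicting anchors")
})

test_that("RNK and GMT files round-trip", {
  ranking <- sprintf("g%02d", sample(1:30))
  path <- withr::local_tempfile(fileext = ".rnk")
  write_rnk(ranking, path)
  expect_equal(read_rnk(path), ranking)

  sets <- list(QUERY_UP = c("a", "b"), QUERY_DOWN = c("c", "d", "e"))
  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, gmt)
  expect_equal(read_gmt(gmt), sets)
})
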