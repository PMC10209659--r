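fixture_library <- function(n = 40L) {
  key <- sprintf("searchlib_%d", n)
  if (is.null(.fixture_cache[[key]])) {
    pairs <- cached_pairs(n)
    .fixture_cache[[key]] <- list(
      pairs = pairs,
      lib = build_library(lapply(pairs, `[[`, "structure"),
                          function(st) pseudo_fragment_spectrum(st))
    )
  }
  .fixture_cache[[key]]
}

test_that("self-queries retrieve their own record at rank 1 with score 1", {
  fx <- fixture_library()
  for (p in fx$pairs[1:10]) {
    res <- search_by_formula(fx$lib, p$spectrum, p$structure$formula,
                             correct_id = p$id)
    expect_equal(res$correct_rank, 1L)
    expect_equal(res$candidates$id[1], p$id)
    expect_equal(res$candidates$similarity[1], 1.0)

    bf <- search_brute_force(fx$lib, p$spectrum, correct_id = p$id)
    expect_equal(bf$correct_rank, 1L)
    expect_equal(bf$n_candidates, length(fx$lib$records))
  }
})

test_that("an exact match outranks an orthogonal candidate", {
  q <- peaks_to_vector(cbind(c(57, 91), c(1, 0.4)))
  ortho <- peaks_to_vector(cbind(c(300, 350), c(1, 1)))
  lib <- manual_library(c("match", "other"), c("C6H12", "C6H12"),
                        list(q, ortho))
  res <- search_by_formula(lib, q, "C6H12", correct_id = "match")
  expect_equal(res$candidates$id, c("match", "other"))
  expect_equal(res$candidates$similarity, c(1, 0))
  expect_equal(res$correct_rank, 1L)
})

test_that("candidate scores are non-increasing and consistent across modes", {
  fx <- fixture_library()
  for (p in fx$pairs[c(3, 11, 27)]) {
    noisy <- pseudo_fragment_spectrum(p$structure, noise_sd = 0.05, seed = 1)
    two_step <- search_by_formula(fx$lib, noisy, p$structure$formula,
                                  correct_id = p$id)
    expect_true(all(diff(two_step$candidates$similarity) <= 0))

    # restriction of the brute-force ranking to the formula bucket
    bf <- search_brute_force(fx$lib, noisy, correct_id = p$id)
    restricted <- bf$candidates[bf$candidates$formula ==
                                  hill_formula(p$structure$formula), ]
    rownames(restricted) <- NULL
    expect_equal(restricted, two_step$candidates)
  }
})

test_that("two-step ranking equals an exhaustive pairwise-cosine sort", {
  fx <- fixture_library()
  lib <- fx$lib
  formulas <- vapply(lib$records, `[[`, "", "formula")
  q <- pseudo_fragment_spectrum(fx$pairs[[5]]$structure, noise_sd = 0.1,
                                seed = 3)
  f <- fx$pairs[[5]]$structure$formula
  res <- search_by_formula(lib, q, f)

  bucket <- lib$records[formulas == hill_formula(f)]
  sims <- vapply(bucket, function(r) cosine_similarity(q, r$spectrum), 0)
  ids <- vapply(bucket, `[[`, "", "id")
  ord <- order(-sims, ids)
  expect_equal(res$candidates$id, ids[ord])
  expect_equal(res$candidates$similarity, sims[ord])

  # brute force against an independent full sort
  bf <- search_brute_force(lib, q)
  all_sims <- vapply(lib$records, function(r) cosine_similarity(q, r$spectrum), 0)
  all_ids <- vapply(lib$records, `[[`, "", "id")
  full <- order(-all_sims, all_ids)
  expect_equal(bf$candidates$id[1:10], all_ids[full][1:10])
  expect_equal(bf$candidates$similarity, all_sims[full])
})

test_that("score ties break by ascending identifier and report the worst rank", {
  s <- peaks_to_vector(cbind(c(43, 57), c(1, 0.7)))
  other <- peaks_to_vector(cbind(c(43, 57, 91), c(1, 0.7, 0.2)))
  lib <- manual_library(c("zeta", "alpha", "near"), rep("C4H10", 3),
                        list(s, s, other))
  res <- search_by_formula(lib, s, "C4H10", correct_id = "alpha")
  expect_equal(res$candidates$id, c("alpha", "zeta", "near"))
  # both tied records share the conservative worst rank
  expect_equal(res$correct_rank, 2L)
  res2 <- search_by_formula(lib, s, "C4H10", correct_id = "zeta")
  expect_equal(res2$correct_rank, 2L)
})

test_that("adding a weaker candidate never worsens the correct rank", {
  q <- peaks_to_vector(cbind(c(50, 64, 91), c(1, 0.5, 0.3)))
  strong <- peaks_to_vector(cbind(c(50, 64), c(1, 0.5)))
  weak <- peaks_to_vector(cbind(c(200, 230), c(1, 0.2)))
  lib1 <- manual_library(c("correct", "rival"), rep("C7H8", 2),
                         list(strong, weak))
  r1 <- search_by_formula(lib1, q, "C7H8", correct_id = "correct")
  lib2 <- manual_library(c("correct", "rival", "extra"), rep("C7H8", 3),
                         list(strong, weak,
                              peaks_to_vector(cbind(c(400, 410), c(1, 1)))))
  r2 <- search_by_formula(lib2, q, "C7H8", correct_id = "correct")
  expect_lte(r2$correct_rank, r1$correct_rank)
  expect_equal(r2$n_candidates, 3L)
})

test_that("empty formula buckets give empty results, not errors", {
  fx <- fixture_library()
  res <- search_by_formula(fx$lib, fx$pairs[[1]]$spectrum, "C60H120O30")
  expect_equal(res$n_candidates, 0L)
  expect_equal(nrow(res$candidates), 0L)
})

test_that("rank evaluation reproduces the inclusive percentile rule", {
  # 1000 same-formula candidates; the query ranks the correct record 10th
  ids <- sprintf("cand%04d", 1:1000)
  spectra <- vector("list", 1000L)
  for (i in 1:9) spectra[[i]] <- peaks_to_vector(cbind(20 + i, 1))
  spectra[[10]] <- peaks_to_vector(cbind(500, 1))
  spectra[[11]] <- peaks_to_vector(cbind(c(30, 31), c(1, 1)))
  for (i in 12:1000) spectra[[i]] <- peaks_to_vector(cbind(c(600 + (i %% 300)), 1))
  lib <- manual_library(ids, rep("C10H22", 1000), spectra)

  query <- peaks_to_vector(cbind(c(21:29, 500), c(rep(1, 9), 0.5)))
  ev <- evaluate_ranks(lib, list(list(spectrum = query, formula = "C10H22",
                                      correct_id = "cand0010")))
  expect_equal(ev$per_query$rank, 10L)
  expect_equal(ev$per_query$n_candidates, 1000L)
  agg <- setNames(ev$aggregate$count, ev$aggregate$category)
  expect_equal(unname(agg[["top"]]), 0L)
  expect_equal(unname(agg[["top1"]]), 1L)   # rank 10 of 1000: within top 1%
  expect_equal(unname(agg[["top5"]]), 1L)
  expect_equal(unname(agg[["top10"]]), 1L)

  # boundary: rank exactly ceil(0.01 * n) is inclusive; one worse is not
  # (the extra bin-30 peak pulls cand0011 above the correct record)
  ev11 <- evaluate_ranks(lib, list(list(
    spectrum = peaks_to_vector(cbind(c(21:30, 500), c(rep(1, 10), 0.5))),
    formula = "C10H22", correct_id = "cand0010")))
  expect_equal(ev11$per_query$rank, 11L)
  agg11 <- setNames(ev11$aggregate$count, ev11$aggregate$category)
  expect_equal(unname(agg11[["top1"]]), 0L)
})

test_that("aggregate fractions recount from the per-query table", {
  fx <- fixture_library()
  queries <- lapply(fx$pairs[1:25], function(p) {
    list(spectrum = pseudo_fragment_spectrum(p$structure, noise_sd = 0.08,
                                             seed = match(p$id, vapply(fx$pairs, `[[`, "", "id"))),
         formula = p$structure$formula, correct_id = p$id)
  })
  ev <- evaluate_ranks(fx$lib, queries)
  per <- ev$per_query
  expect_true(all(is.na(per$error)))
  # independent recount of every aggregate cell
  expect_equal(ev$aggregate$count[ev$aggregate$category == "top"],
               sum(per$rank == 1L))
  for (spec in list(c("top1", 0.01), c("top5", 0.05), c("top10", 0.10))) {
    expect_equal(
      ev$aggregate$count[ev$aggregate$category == spec[1]],
      sum(per$rank <= ceiling(as.numeric(spec[2]) * per$n_candidates)))
  }
  expect_equal(ev$aggregate$fraction,
               ev$aggregate$count / ev$aggregate$n_evaluated)
})

test_that("bucket-size restriction and missing identifiers are handled", {
  fx <- fixture_library()
  queries <- list(
    list(spectrum = fx$pairs[[1]]$spectrum,
         formula = fx$pairs[[1]]$structure$formula,
         correct_id = fx$pairs[[1]]$id),
    list(spectrum = fx$pairs[[2]]$spectrum,
         formula = fx$pairs[[2]]$structure$formula,
         correct_id = "not-a-record")
  )
  ev <- evaluate_ranks(fx$lib, queries)
  expect_equal(ev$per_query$error[2], "correct identifier not in library")
  expect_equal(ev$aggregate$n_evaluated[1], 1L)

  ev_min <- evaluate_ranks(fx$lib, queries[1], min_bucket = 100L)
  expect_equal(ev_min$aggregate$n_evaluated[1], 0L)
})
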