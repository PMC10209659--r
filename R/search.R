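# Two-step library search (formula filter, then cosine ranking),
# brute-force search, and rank-percentile evaluation.

.rank_records <- function(records, query, correct_id = NULL) {
  if (!length(records)) {
    return(structure(list(
      query_id = NULL,
      candidates = data.frame(id = character(0), formula = character(0),
                              similarity = numeric(0)),
      n_candidates = 0L, correct_rank = NA_integer_
    ), class = "search_result"))
  }
  ids <- vapply(records, `[[`, "", "id")
  formulas <- vapply(records, `[[`, "", "formula")
  sims <- vapply(records, function(r) cosine_similarity(query, r$spectrum), 0)
  # descending similarity; ties broken by ascending identifier
  ord <- order(-sims, ids)
  candidates <- data.frame(id = ids[ord], formula = formulas[ord],
                           similarity = sims[ord])
  correct_rank <- NA_integer_
  if (!is.null(correct_id)) {
    hit <- match(correct_id, ids)
    if (!is.na(hit)) {
      s <- sims[hit]
      # conservative: the worst rank among candidates tied at this score
      correct_rank <- sum(sims > s) + sum(sims == s)
    }
  }
  structure(list(query_id = correct_id, candidates = candidates,
                 n_candidates = length(records),
                 correct_rank = correct_rank),
            class = "search_result")
}

#' @export
print.search_result <- function(x, n = 5L, ...) {
  cat(sprintf("<search_result> %d candidate(s)%s\n", x$n_candidates,
              if (is.na(x$correct_rank)) ""
              else sprintf(", correct at rank %d", x$correct_rank)))
  if (x$n_candidates) print(head(x$candidates, n))
  invisible(x)
}

#' Two-step library search
#'
#' Step one extracts the candidates sharing the query's molecular formula
#' from the library index; step two ranks them by cosine similarity to the
#' query spectrum (descending; ties broken by ascending identifier).
#'
#' @param library A `pei_library` from [build_library()].
#' @param query_spectrum Query spectrum (`ei_spectrum` or length-996
#'   vector) with at least one nonzero bin.
#' @param formula The query's molecular formula (determined upstream, e.g.
#'   from soft-ionization accurate mass; any element order accepted).
#' @param correct_id Optional identifier of the known-correct record; when
#'   given, `correct_rank` reports its 1-based rank (under score ties, the
#'   worst rank within the tied block).
#' @return A `search_result`: `candidates` (data frame of `id`, `formula`,
#'   `similarity`), `n_candidates`, `correct_rank`. An empty formula bucket
#'   yields an empty result, not an error.
#' @export
search_by_formula <- function(library, query_spectrum, formula,
                              correct_id = NULL) {
  stopifnot(inherits(library, "pei_library"))
  .rank_records(lookup_formula(library, formula), query_spectrum, correct_id)
}

#' Brute-force library search
#'
#' Ranks every record in the library by cosine similarity to the query,
#' with no formula filter. Restricting the result to one formula reproduces
#' [search_by_formula()] exactly.
#'
#' @inheritParams search_by_formula
#' @return A `search_result` over the whole library.
#' @export
search_brute_force <- function(library, query_spectrum, correct_id = NULL) {
  stopifnot(inherits(library, "pei_library"))
  .rank_records(library$records, query_spectrum, correct_id)
}

#' Rank-percentile evaluation of library search accuracy
#'
#' Runs [search_by_formula()] for every query and tabulates where the
#' correct structure lands among its same-formula candidates. The rank
#' percentile is `rank / bucket size`; a query at rank exactly
#' `ceiling(p * n)` counts as within the top `p` (boundary inclusive), so
#' rank 10 of 1000 candidates is within the top 1%. "Top" means rank 1
#' exactly.
#'
#' @param library A `pei_library`.
#' @param queries List of `list(spectrum, formula, correct_id)` queries.
#' @param min_bucket Restrict the aggregate to queries whose formula bucket
#'   holds at least this many candidates (0 = no restriction; large-scale
#'   evaluations conventionally use 100).
#' @return List with `per_query` (data frame: `correct_id`, `formula`,
#'   `n_candidates`, `rank`, `error`) and `aggregate` (data frame with
#'   `n_evaluated` and counts/fractions at `top`, `top1`, `top5`, `top10`
#'   percent).
#' @export
evaluate_ranks <- function(library, queries, min_bucket = 0L) {
  stopifnot(inherits(library, "pei_library"))
  all_ids <- vapply(library$records, `[[`, "", "id")
  per <- lapply(queries, function(q) {
    stopifnot(!is.null(q$spectrum), !is.null(q$formula),
              !is.null(q$correct_id))
    if (!(q$correct_id %in% all_ids)) {
      return(data.frame(correct_id = q$correct_id, formula = q$formula,
                        n_candidates = NA_integer_, rank = NA_integer_,
                        error = "correct identifier not in library"))
    }
    res <- search_by_formula(library, q$spectrum, q$formula, q$correct_id)
    err <- if (is.na(res$correct_rank)) {
      "correct identifier not in formula bucket"
    } else NA_character_
    data.frame(correct_id = q$correct_id, formula = q$formula,
               n_candidates = res$n_candidates, rank = res$correct_rank,
               error = err)
  })
  per <- do.call(rbind, per)
  ok <- is.na(per$error) & per$n_candidates >= min_bucket
  ranks <- per$rank[ok]
  sizes <- per$n_candidates[ok]
  n_eval <- sum(ok)
  within <- function(p) sum(ranks <= ceiling(p * sizes))
  counts <- c(top = sum(ranks == 1L), top1 = within(0.01),
              top5 = within(0.05), top10 = within(0.10))
  aggregate <- data.frame(
    n_evaluated = n_eval,
    category = names(counts),
    count = as.integer(counts),
    fraction = if (n_eval) unname(counts) / n_eval else NA_real_
  )
  list(per_query = per, aggregate = aggregate)
}
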