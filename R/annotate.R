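#' Annotate clones by exact CDR3 amino-acid identity
#'
#' A clone is annotated if and only if its CDR3 amino-acid sequence equals
#' (case-sensitive, full string) the CDR3aa of at least one database record;
#' all matching records are listed and their disease tags unioned.
#'
#' @param repertoire a `repertoire`.
#' @param db antibody database from [read_antibody_db()].
#' @return data.frame with `clone_key`, `cdr3_aa`, and list-columns
#'   `matched_ids`, `diseases`; one row per annotated clone.
#' @export
match_clones_to_db <- function(repertoire, db) {
  assert_that(nrow(db) > 0L, "antibody database is empty")
  cl <- repertoire$clones
  by_cdr3 <- split(seq_len(nrow(db)), db$cdr3_aa)
  hit <- !is.na(cl$cdr3_aa) & cl$cdr3_aa %in% names(by_cdr3)
  cl <- cl[hit, , drop = FALSE]
  out <- data.frame(clone_key = cl$clone_key, cdr3_aa = cl$cdr3_aa,
                    stringsAsFactors = FALSE)
  out$matched_ids <- lapply(cl$cdr3_aa, function(aa) db$id[by_cdr3[[aa]]])
  out$diseases <- lapply(cl$cdr3_aa, function(aa) {
    sort(unique(unlist(db$diseases[by_cdr3[[aa]]], use.names = FALSE)))
  })
  rownames(out) <- NULL
  out
}

#' Hypergeometric upper-tail probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric with population size
#' `N`, `K` successes and `n` draws, the over-representation p-value of
#' observing `k` or more tagged items. `k = 0` gives 1.
#'
#' @param k observed successes in the sample.
#' @param n sample size.
#' @param K successes in the population.
#' @param N population size.
#' @return probability in [0, 1].
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  for (v in list(k, n, K, N)) {
    assert_that(length(v) == 1L && !is.na(v) && v == as.integer(v) && v >= 0,
                "arguments must be single non-negative integers")
  }
  assert_that(n <= N && K <= N, "need n <= N and K <= N")
  assert_that(k <= min(n, K), "need k <= min(n, K)")
  if (k == 0L) return(1.0)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment: sort ascending, multiply by m/rank,
#' enforce monotonicity from the largest down, cap at 1, return in input
#' order.
#'
#' @param p_values numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p_values) {
  assert_that(is.numeric(p_values) && !anyNA(p_values) &&
                all(p_values >= 0 & p_values <= 1),
              "p-values must be in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Disease enrichment of annotated clones
#'
#' Tests whether the diseases tagged on matched clones are over-represented
#' relative to the antibody database, with a hypergeometric upper tail per
#' disease and Benjamini-Hochberg correction across the tested diseases.
#' Counting is clone-level: the universe `N` is the number of database
#' records carrying at least one disease tag (or all records with
#' `universe = "all"`), `K` the records tagged with the disease, `n` the
#' annotated clones carrying at least one disease tag, and `k` the annotated
#' clones tagged with the disease (each clone counted once per disease).
#' Only diseases with `k >= 1` are tested. In the degenerate case `k > K`
#' (several distinct clones matching the same record) the observation lies
#' outside the hypergeometric support and the p-value is 0.
#'
#' @param annotations output of [match_clones_to_db()].
#' @param db the same antibody database.
#' @param significance_cutoff adjusted-p threshold for the `significant`
#'   flag (default 0.05).
#' @param universe `"tagged"` (records with >= 1 disease tag; default) or
#'   `"all"` (every database record).
#' @return data.frame with one row per tested disease: `disease, k, n, K, N,
#'   p_value, p_adj, significant`, sorted by `p_adj` then disease. Empty
#'   (with warning) when no annotated clone carries a disease tag.
#' @export
disease_enrichment <- function(annotations, db, significance_cutoff = 0.05,
                               universe = c("tagged", "all")) {
  universe <- match.arg(universe)
  assert_that(significance_cutoff > 0 && significance_cutoff < 1,
              "significance cutoff must be in (0, 1)")
  tagged_db <- lengths(db$diseases) > 0L
  N <- if (universe == "tagged") sum(tagged_db) else nrow(db)
  db_tags <- db$diseases
  K_tab <- table(unlist(db_tags, use.names = FALSE))
  tagged_ann <- lengths(annotations$diseases) > 0L
  n <- sum(tagged_ann)
  if (n == 0L) {
    warning("no annotated clone carries a disease tag")
    return(data.frame(disease = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      p_adj = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  k_tab <- table(unlist(annotations$diseases[tagged_ann], use.names = FALSE))
  diseases <- names(k_tab)
  k <- as.integer(k_tab)
  K <- as.integer(K_tab[diseases])
  p <- vapply(seq_along(diseases), function(i) {
    if (k[i] > K[i]) return(0.0)  # outside the support: see details
    hypergeom_upper_tail(k[i], n, K[i], N)
  }, 0)
  p_adj <- bh_adjust(p)
  out <- data.frame(disease = diseases, k = k, n = n, K = K, N = N,
                    p_value = p, p_adj = p_adj,
                    significant = p_adj < significance_cutoff,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_adj, out$disease), , drop = FALSE]
  rownames(out) <- NULL
  out
}
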