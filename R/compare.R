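#' Select reference repertoires by metadata criteria
#'
#' Filters a catalog of repertoires by exact match on each provided metadata
#' criterion (e.g. amplification strategy, tissue, health condition, primer
#' locations, read length, isotype, age, sex); unspecified criteria match
#' everything. The result is ordered by sample id.
#'
#' @param catalog list of `repertoire` objects carrying metadata.
#' @param criteria named list of metadata values to require.
#' @param label group label, `"reference"` or `"experimental"`.
#' @return a `sample_group`: list with `label`, `repertoires`,
#'   `selection_criteria`.
#' @export
select_reference <- function(catalog, criteria = list(),
                             label = "reference") {
  keep <- vapply(catalog, function(rep) {
    all(vapply(names(criteria), function(k) {
      !is.null(rep$metadata[[k]]) &&
        identical(as.character(rep$metadata[[k]]),
                  as.character(criteria[[k]]))
    }, TRUE))
  }, TRUE)
  sel <- catalog[keep]
  if (length(sel) == 0L) {
    stop("no repertoire matches the selection criteria; relax them",
         call. = FALSE)
  }
  ids <- vapply(sel, `[[`, "", "sample_id")
  assert_that(!anyDuplicated(ids), "duplicate sample ids in catalog")
  sample_group(sel[order(ids)], label, criteria)
}

#' Construct a sample group
#'
#' @param repertoires list of `repertoire` objects.
#' @param label `"experimental"` or `"reference"`.
#' @param selection_criteria criteria record used to select the group.
#' @return a `sample_group`.
#' @export
sample_group <- function(repertoires, label = "experimental",
                         selection_criteria = list()) {
  assert_that(label %in% c("experimental", "reference"),
              "label must be experimental or reference")
  ids <- vapply(repertoires, `[[`, "", "sample_id")
  assert_that(!anyDuplicated(ids), "duplicate sample ids in group")
  structure(list(label = label, repertoires = repertoires,
                 selection_criteria = selection_criteria),
            class = "sample_group")
}

#' @export
print.sample_group <- function(x, ...) {
  cat(sprintf("<sample_group> %s: %d sample(s)\n", x$label,
              length(x$repertoires)))
  invisible(x)
}

group_sample_ids <- function(group) {
  vapply(group$repertoires, `[[`, "", "sample_id")
}

#' Compute a named feature vector for one repertoire
#'
#' Common currency for group comparison: each feature name maps to a named
#' numeric vector over categories (genes, lengths, junction sites, or a
#' single index).
#'
#' @param repertoire a `repertoire`.
#' @param feature_name one of `v_usage`, `d_usage`, `j_usage`,
#'   `cdr3_length_nt`, `cdr3_length_aa`, `shannon`, `simpson`, `d50`,
#'   `top_fraction`, `deletion_mean`, `insertion_mean`.
#' @return named numeric vector.
#' @export
repertoire_feature <- function(repertoire, feature_name) {
  switch(feature_name,
    v_usage = gene_usage(repertoire, "V"),
    d_usage = gene_usage(repertoire, "D"),
    j_usage = gene_usage(repertoire, "J"),
    cdr3_length_nt = cdr3_length_distribution(repertoire, "nt"),
    cdr3_length_aa = cdr3_length_distribution(repertoire, "aa"),
    shannon = c(shannon = unname(diversity_indices(repertoire)["shannon"])),
    simpson = c(simpson = unname(diversity_indices(repertoire)["simpson"])),
    d50 = c(d50 = unname(diversity_indices(repertoire)["d50"])),
    top_fraction = c(top_fraction = top_clone_fraction(repertoire)),
    deletion_mean = junction_site_means(repertoire, "deletion"),
    insertion_mean = junction_site_means(repertoire, "insertion"),
    stop("unknown feature '", feature_name, "'", call. = FALSE)
  )
}

junction_site_means <- function(repertoire, what) {
  prof <- suppressWarnings(junction_profile(repertoire))
  freqs <- if (what == "deletion") prof$deletion_freq else prof$insertion_freq
  vapply(freqs, function(f) {
    if (length(f) == 0L) return(NA_real_)
    sum(as.numeric(names(f)) * f)
  }, 0)
}

#' Compare a feature between an experimental and a reference group
#'
#' Per category (the union over both groups; values absent for a sample are
#' treated as 0), summarises the reference group with a five-number summary
#' (linear-interpolation quantiles) and reports each experimental sample's
#' value unmodified.
#'
#' @param exp,ref `sample_group` objects.
#' @param feature_name see [repertoire_feature()].
#' @return a `feature_comparison`: list with `feature_name`, `categories`,
#'   `reference_summary` (data.frame category, min, q1, median, q3, max, n)
#'   and `experimental_points` (matrix category x sample).
#' @export
compare_feature <- function(exp, ref, feature_name) {
  get_vals <- function(group) {
    vals <- lapply(group$repertoires, function(rep) {
      v <- tryCatch(repertoire_feature(rep, feature_name),
                    error = function(e) {
                      stop("feature '", feature_name,
                           "' unavailable for sample ", rep$sample_id, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
      v
    })
    names(vals) <- group_sample_ids(group)
    vals
  }
  exp_vals <- get_vals(exp)
  ref_vals <- get_vals(ref)
  categories <- sort(unique(c(unlist(lapply(exp_vals, names)),
                              unlist(lapply(ref_vals, names)))))
  densify <- function(v) {
    out <- setNames(numeric(length(categories)), categories)
    out[names(v)] <- v
    out
  }
  ref_mat <- vapply(ref_vals, densify, numeric(length(categories)))
  exp_mat <- vapply(exp_vals, densify, numeric(length(categories)))
  if (length(categories) == 1L) {
    ref_mat <- matrix(ref_mat, nrow = 1L,
                      dimnames = list(categories, names(ref_vals)))
    exp_mat <- matrix(exp_mat, nrow = 1L,
                      dimnames = list(categories, names(exp_vals)))
  }
  qs <- t(apply(ref_mat, 1L, function(x) {
    quantile(x, probs = c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  }))
  reference_summary <- data.frame(
    category = categories, min = qs[, 1L], q1 = qs[, 2L], median = qs[, 3L],
    q3 = qs[, 4L], max = qs[, 5L], n = ncol(ref_mat),
    stringsAsFactors = FALSE
  )
  rownames(reference_summary) <- NULL
  structure(list(feature_name = feature_name, categories = categories,
                 reference_summary = reference_summary,
                 experimental_points = exp_mat),
            class = "feature_comparison")
}

#' @export
print.feature_comparison <- function(x, ...) {
  cat(sprintf("<feature_comparison> %s: %d categorie(s), %d reference, %d experimental sample(s)\n",
              x$feature_name, length(x$categories),
              x$reference_summary$n[1], ncol(x$experimental_points)))
  invisible(x)
}

sharing_keys <- function(repertoire, sharing_key) {
  cl <- repertoire$clones
  keys <- switch(sharing_key,
    cdr3aa = cl$cdr3_aa[!is.na(cl$cdr3_aa)],
    cdr3nt = cl$cdr3_nt,
    vj_cdr3nt = paste(cl$v_gene, cl$j_gene, cl$cdr3_nt, sep = "|"),
    stop("unknown sharing key '", sharing_key, "'", call. = FALSE)
  )
  unique(keys)
}

#' Detect public (convergent) clones across samples
#'
#' A sharing key (CDR3 amino-acid sequence by default) counts once per
#' sample. Keys present in at least `min_share` samples overall and in at
#' least one experimental sample are reported: *intragroup* when all
#' carriers are experimental samples, *intergroup* when carriers span both
#' groups. Output is sorted by total carrier count (descending), then key.
#'
#' @param exp `sample_group` of experimental samples.
#' @param ref `sample_group` of reference samples (may be empty).
#' @param sharing_key `"cdr3aa"`, `"cdr3nt"` or `"vj_cdr3nt"`.
#' @param min_share minimum total number of carrying samples (>= 2).
#' @return data.frame with `key`, `class`, `n_exp`, `n_ref`, and
#'   list-columns `exp_samples`, `ref_samples`.
#' @export
detect_public_clones <- function(exp, ref = NULL,
                                 sharing_key = c("cdr3aa", "cdr3nt",
                                                 "vj_cdr3nt"),
                                 min_share = 2L) {
  sharing_key <- match.arg(sharing_key)
  assert_that(min_share >= 2L, "min_share must be >= 2")
  exp_keys <- lapply(exp$repertoires, sharing_keys, sharing_key)
  names(exp_keys) <- group_sample_ids(exp)
  ref_keys <- if (is.null(ref)) list() else {
    k <- lapply(ref$repertoires, sharing_keys, sharing_key)
    names(k) <- group_sample_ids(ref)
    k
  }
  key_samples <- function(keys_by_sample) {
    if (length(keys_by_sample) == 0L) return(list())
    df <- data.frame(
      key = unlist(keys_by_sample, use.names = FALSE),
      sample = rep.int(names(keys_by_sample), lengths(keys_by_sample)),
      stringsAsFactors = FALSE
    )
    split(df$sample, df$key)
  }
  exp_map <- key_samples(exp_keys)
  ref_map <- key_samples(ref_keys)
  keys <- names(exp_map)  # a public clone must appear in >=1 exp sample
  n_exp <- lengths(exp_map[keys])
  n_ref <- ifelse(keys %in% names(ref_map), lengths(ref_map[keys]), 0L)
  keep <- (n_exp + n_ref) >= min_share
  keys <- keys[keep]; n_exp <- n_exp[keep]; n_ref <- n_ref[keep]
  ord <- order(-(n_exp + n_ref), keys)
  keys <- keys[ord]; n_exp <- n_exp[ord]; n_ref <- n_ref[ord]
  out <- data.frame(key = keys,
                    class = ifelse(n_ref == 0L, "intragroup", "intergroup"),
                    n_exp = as.integer(n_exp), n_ref = as.integer(n_ref),
                    stringsAsFactors = FALSE)
  out$exp_samples <- lapply(keys, function(k) sort(exp_map[[k]]))
  out$ref_samples <- lapply(keys, function(k) {
    s <- ref_map[[k]]
    if (is.null(s)) character() else sort(s)
  })
  rownames(out) <- NULL
  out
}
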