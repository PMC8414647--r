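CONFIG_KEYS <- c("input", "germline", "analysis", "reference",
                 "antibody_db", "public_clones", "enrichment", "output",
                 "seed")

#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration, applies defaults, and validates keys, paths
#' and bounds. Schema (top-level keys):
#' \describe{
#'   \item{input}{`clone_tables`: named map sample id -> TSV path (or a
#'     list of paths, ids derived from file names); `dialect`: one of
#'     native/airr/mixcr (default native).}
#'   \item{germline}{`fasta` and `boundaries` paths (optional; required for
#'     hypermutation profiling).}
#'   \item{analysis}{`use_c_gene` (default TRUE), `isotype` (optional
#'     isotype selection), `shm_isotypes` (isotypes to profile; default all
#'     present).}
#'   \item{reference}{`catalog_dir`: directory of native TSVs plus a
#'     `metadata.tsv` with a `sample_id` column; `criteria`: metadata
#'     equality filters.}
#'   \item{antibody_db}{path to the antibody database TSV.}
#'   \item{public_clones}{`sharing_key` (default cdr3aa), `min_share`
#'     (default 2).}
#'   \item{enrichment}{`cutoff` (default 0.05), `universe` (tagged/all).}
#'   \item{output}{`dir`: output directory (mandatory).}
#'   \item{seed}{integer seed (default 1).}
#' }
#'
#' @param path YAML config path.
#' @return validated config list of class `run_config`.
#' @export
validate_config <- function(path) {
  assert_that(file.exists(path), paste("config file not found:", path))
  cfg <- yaml::read_yaml(path)
  # input paths may be given relative to the config file's directory
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || file.exists(p) || dir.exists(p)) return(p)
    cand <- file.path(base, p)
    if (file.exists(cand) || dir.exists(cand)) cand else p
  }
  if (!is.null(cfg$input$clone_tables)) {
    cfg$input$clone_tables <- lapply(cfg$input$clone_tables, resolve)
  }
  cfg$germline$fasta <- resolve(cfg$germline$fasta)
  cfg$germline$boundaries <- resolve(cfg$germline$boundaries)
  cfg$reference$catalog_dir <- resolve(cfg$reference$catalog_dir)
  cfg$antibody_db <- resolve(cfg$antibody_db)
  unknown <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  assert_that(!is.null(cfg$input$clone_tables),
              "config must set input: clone_tables")
  assert_that(!is.null(cfg$output$dir), "config must set output: dir")
  tables <- cfg$input$clone_tables
  if (is.null(names(tables))) {
    names(tables) <- tools::file_path_sans_ext(basename(unlist(tables)))
  }
  tables <- lapply(tables, identity)
  for (p in unlist(tables)) {
    assert_that(file.exists(p), paste("clone table not found:", p))
  }
  dialect <- cfg$input$dialect %||% "native"
  assert_that(dialect %in% c("native", "airr", "mixcr"),
              paste("unknown dialect:", dialect))
  if (!is.null(cfg$germline)) {
    for (p in c(cfg$germline$fasta, cfg$germline$boundaries)) {
      assert_that(file.exists(p), paste("germline file not found:", p))
    }
  }
  if (!is.null(cfg$reference)) {
    assert_that(dir.exists(cfg$reference$catalog_dir),
                paste("reference catalog not found:",
                      cfg$reference$catalog_dir))
  }
  if (!is.null(cfg$antibody_db)) {
    assert_that(file.exists(cfg$antibody_db),
                paste("antibody db not found:", cfg$antibody_db))
  }
  min_share <- cfg$public_clones$min_share %||% 2L
  assert_that(min_share >= 2L, "public_clones: min_share must be >= 2")
  sharing_key <- cfg$public_clones$sharing_key %||% "cdr3aa"
  assert_that(sharing_key %in% c("cdr3aa", "cdr3nt", "vj_cdr3nt"),
              paste("unknown sharing key:", sharing_key))
  cutoff <- cfg$enrichment$cutoff %||% 0.05
  assert_that(cutoff > 0 && cutoff < 1,
              "enrichment cutoff must be in (0, 1)")
  iso <- cfg$analysis$isotype
  if (!is.null(iso)) {
    assert_that(iso %in% ISOTYPE_LEVELS, paste("unknown isotype:", iso))
  }
  structure(list(
    clone_tables = tables, dialect = dialect,
    germline_fasta = cfg$germline$fasta,
    germline_boundaries = cfg$germline$boundaries,
    use_c_gene = isTRUE(cfg$analysis$use_c_gene %||% TRUE),
    isotype = iso,
    shm_isotypes = cfg$analysis$shm_isotypes,
    reference_dir = cfg$reference$catalog_dir,
    reference_criteria = cfg$reference$criteria %||% list(),
    antibody_db = cfg$antibody_db,
    sharing_key = sharing_key, min_share = as.integer(min_share),
    enrichment_cutoff = cutoff,
    enrichment_universe = cfg$enrichment$universe %||% "tagged",
    outdir = cfg$output$dir, seed = as.integer(cfg$seed %||% 1L)
  ), class = "run_config")
}

#' Load a reference catalog directory
#'
#' The directory holds one native-dialect TSV per sample plus a
#' `metadata.tsv` whose `sample_id` column names each sample's file
#' (`<sample_id>.tsv`); remaining columns become repertoire metadata.
#'
#' @param dir catalog directory.
#' @param use_c_gene clone-key setting applied while clustering.
#' @return list of `repertoire` objects.
#' @export
load_reference_catalog <- function(dir, use_c_gene = TRUE) {
  meta_path <- file.path(dir, "metadata.tsv")
  assert_that(file.exists(meta_path),
              paste("reference catalog lacks metadata.tsv in", dir))
  meta <- read.delim(meta_path, sep = "\t", stringsAsFactors = FALSE,
                     colClasses = "character")
  assert_that("sample_id" %in% names(meta),
              "metadata.tsv must have a sample_id column")
  lapply(seq_len(nrow(meta)), function(i) {
    sid <- meta$sample_id[i]
    recs <- read_clone_table(file.path(dir, paste0(sid, ".tsv")), "native")
    md <- as.list(meta[i, setdiff(names(meta), "sample_id"), drop = FALSE])
    cluster_clones(recs, sample_id = sid, use_c_gene = use_c_gene,
                   metadata = md)
  })
}

COMPARE_FEATURES <- c("v_usage", "d_usage", "j_usage", "cdr3_length_nt",
                      "d50", "deletion_mean", "insertion_mean")

#' Run the analysis pipeline
#'
#' Executes the pipeline stages in order — io, clonotype, features, shm,
#' compare (reference selection, feature comparison, public clones),
#' annotate (database matching plus disease enrichment) — each writing its
#' TSV outputs under the configured output directory, and finishes with a
#' `manifest.json` listing every output file with its row count and the
#' status of each stage. Stages without configured inputs (no germline, no
#' reference catalog, no antibody database) are skipped and noted in the
#' manifest. A stage failure stops subsequent stages; partial outputs are
#' retained and the failing stage is named in the manifest.
#'
#' @param config a `run_config` from [validate_config()].
#' @param stages subset of stages to run (default all).
#' @return invisibly, list with `status` (0 on success) and `manifest`.
#' @export
run_pipeline <- function(config,
                         stages = c("features", "shm", "compare",
                                    "annotate")) {
  assert_that(inherits(config, "run_config"),
              "config must come from validate_config()")
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(stages = list(), files = list())
  status <- 0L
  add_files <- function(paths) {
    for (nm in names(paths)) {
      p <- paths[[nm]]
      n <- length(readLines(p, warn = FALSE)) - 1L
      manifest$files[[basename(p)]] <<- list(path = p, rows = n)
    }
  }
  fail <- function(stage, e) {
    manifest$stages[[stage]] <<- paste("failed:", conditionMessage(e))
    status <<- 1L
  }

  set.seed(config$seed)
  germline <- NULL
  repertoires <- NULL
  tryCatch({
    if (!is.null(config$germline_fasta)) {
      germline <- read_germline_fasta(config$germline_fasta,
                                      config$germline_boundaries)
    }
    repertoires <- lapply(names(config$clone_tables), function(sid) {
      recs <- read_clone_table(config$clone_tables[[sid]], config$dialect,
                               germline = germline)
      rep <- cluster_clones(recs, sample_id = sid,
                            use_c_gene = config$use_c_gene)
      if (!is.null(config$isotype)) {
        rep$clones <- rep$clones[rep$clones$isotype == config$isotype, ,
                                 drop = FALSE]
        assert_that(nrow(rep$clones) > 0L,
                    paste("no clone of isotype", config$isotype,
                          "in sample", sid))
      }
      rep
    })
    manifest$stages$io <- "ok"
    manifest$stages$clonotype <- "ok"
  }, error = function(e) fail("io", e))

  if (status == 0L && "features" %in% stages) {
    tryCatch({
      add_files(write_feature_tables(repertoires, outdir))
      manifest$stages$features <- "ok"
    }, error = function(e) fail("features", e))
  }

  if (status == 0L && "shm" %in% stages) {
    if (is.null(germline)) {
      manifest$stages$shm <- "skipped: no germline configured"
    } else {
      tryCatch({
        profiles <- list()
        for (rep in repertoires) {
          isotypes <- config$shm_isotypes %||%
            sort(unique(rep$clones$isotype))
          for (iso in isotypes) {
            pr <- suppressWarnings(
              repertoire_shm_profile(rep, germline, iso))
            attr(pr, "sample_id") <- rep$sample_id
            profiles[[length(profiles) + 1L]] <- pr
          }
        }
        add_files(write_shm_tables(profiles, outdir))
        manifest$stages$shm <- "ok"
      }, error = function(e) fail("shm", e))
    }
  }

  if (status == 0L && "compare" %in% stages) {
    tryCatch({
      exp_group <- sample_group(repertoires, "experimental")
      ref_group <- NULL
      if (!is.null(config$reference_dir)) {
        catalog <- load_reference_catalog(config$reference_dir,
                                          config$use_c_gene)
        ref_group <- select_reference(catalog, config$reference_criteria)
        for (feat in COMPARE_FEATURES) {
          cmp <- compare_feature(exp_group, ref_group, feat)
          p <- file.path(outdir, sprintf("comparison_%s.tsv", feat))
          write_comparison(cmp, p)
          add_files(setNames(p, sprintf("comparison_%s", feat)))
        }
      }
      public <- detect_public_clones(exp_group, ref_group,
                                     sharing_key = config$sharing_key,
                                     min_share = config$min_share)
      p <- file.path(outdir, "public_clones.tsv")
      write_public_clones(public, p)
      add_files(c(public_clones = p))
      manifest$stages$compare <- if (is.null(ref_group)) {
        "ok (no reference catalog; intragroup public clones only)"
      } else "ok"
    }, error = function(e) fail("compare", e))
  }

  if (status == 0L && "annotate" %in% stages) {
    if (is.null(config$antibody_db)) {
      manifest$stages$annotate <- "skipped: no antibody database configured"
    } else {
      tryCatch({
        db <- read_antibody_db(config$antibody_db)
        ann_rows <- list(); enr_rows <- list()
        for (rep in repertoires) {
          ann <- match_clones_to_db(rep, db)
          if (nrow(ann) > 0L) {
            a <- ann
            a$sample_id <- rep$sample_id
            ann_rows[[rep$sample_id]] <- a[c("sample_id",
                                             setdiff(names(a), "sample_id"))]
          }
          enr <- suppressWarnings(
            disease_enrichment(ann, db, config$enrichment_cutoff,
                               config$enrichment_universe))
          if (nrow(enr) > 0L) {
            e <- enr
            e$sample_id <- rep$sample_id
            enr_rows[[rep$sample_id]] <- e[c("sample_id",
                                             setdiff(names(e), "sample_id"))]
          }
        }
        ann_all <- do.call(rbind, ann_rows) %||%
          data.frame(sample_id = character(), clone_key = character(),
                     cdr3_aa = character(), matched_ids = character(),
                     diseases = character())
        if (is.data.frame(ann_all) && "matched_ids" %in% names(ann_all) &&
            is.list(ann_all$matched_ids)) {
          ann_all$matched_ids <- collapse_list_col(ann_all$matched_ids)
          ann_all$diseases <- collapse_list_col(ann_all$diseases)
        }
        p <- file.path(outdir, "annotations.tsv")
        write_tsv(ann_all, p); add_files(c(annotations = p))
        enr_all <- do.call(rbind, enr_rows) %||%
          data.frame(sample_id = character(), disease = character(),
                     k = integer(), n = integer(), K = integer(),
                     N = integer(), p_value = numeric(), p_adj = numeric(),
                     significant = logical())
        p <- file.path(outdir, "enrichment.tsv")
        write_enrichment(enr_all, p); add_files(c(enrichment = p))
        manifest$stages$annotate <- "ok"
      }, error = function(e) fail("annotate", e))
    }
  }

  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(status = status, manifest = manifest,
                 manifest_path = manifest_path))
}
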