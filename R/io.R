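# Plain-text artifact I/O. Everything is CSV (UTF-8, comma, '.' decimal)
# with a header row; RDMs carry their stimulus ids as first column and a
# JSON metadata sidecar; ground truth is JSON. write(read(x)) == x for all
# artifact types.

#' Read and write pipeline artifacts
#'
#' CSV/JSON (de)serialisation for every table the pipeline consumes or
#' produces, with validation on read: rating values must lie in 1-9,
#' pattern manifests must not contain duplicate (subject, ROI) keys, and
#' malformed files are reported with the offending entity named.
#'
#' @param x object to write
#' @param path file path
#' @return readers return the validated object; writers return `path`
#'   invisibly
#' @name touchrsa-io
NULL

#' @rdname touchrsa-io
#' @export
write_design_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname touchrsa-io
#' @export
read_design_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$category <- factor(d$category, levels = c("social_positive",
                                              "social_negative",
                                              "nonsocial"))
  validate_design(d)
  d
}

#' @rdname touchrsa-io
#' @export
write_ratings_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname touchrsa-io
#' @export
read_ratings_csv <- function(path) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_ratings(r)
  r
}

#' @rdname touchrsa-io
#' @export
write_questionnaires_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname touchrsa-io
#' @export
read_questionnaires_csv <- function(path) {
  q <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(q))) {
    stop("questionnaire table lacks subject_id/group columns")
  }
  if ("stq_total" %in% names(q) &&
      any(q$stq_total < 20 | q$stq_total > 100)) {
    stop("stq_total outside the attainable 20-100 range")
  }
  q
}

#' @rdname touchrsa-io
#' @param kind,source RDM metadata used when no sidecar is present
#' @export
write_rdm_csv <- function(x, path) {
  stopifnot(is_rdm(x))
  df <- data.frame(stimulus_id = x$labels, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(list(kind = x$kind, source = x$source), meta,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname touchrsa-io
#' @export
read_rdm_csv <- function(path, kind = "model", source = "") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  meta_path <- sub("\\.csv$", ".json", path)
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    kind <- meta$kind %||% kind
    source <- meta$source %||% source
  }
  rdm(m, labels = labels, kind = kind, source = source)
}

#' @rdname touchrsa-io
#' @param patterns nested list of [pattern_set()]s (subject -> ROI)
#' @param dir directory for the `<subject>/<roi>.csv` layout
#' @export
write_patterns <- function(patterns, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (subj in names(patterns)) {
    sdir <- file.path(dir, subj)
    dir.create(sdir, showWarnings = FALSE)
    for (roi in names(patterns[[subj]])) {
      ps <- patterns[[subj]][[roi]]
      rel <- file.path(subj, paste0(roi, ".csv"))
      df <- data.frame(stimulus_id = rownames(ps$matrix), ps$matrix,
                       check.names = FALSE, stringsAsFactors = FALSE)
      utils::write.csv(df, file.path(dir, rel), row.names = FALSE)
      manifest[[length(manifest) + 1L]] <-
        data.frame(subject_id = ps$subject_id, group = ps$group,
                   roi = roi, path = rel, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname touchrsa-io
#' @export
read_patterns <- function(dir) {
  mf_path <- file.path(dir, "manifest.csv")
  if (!file.exists(mf_path)) stop("no manifest.csv under ", dir)
  mf <- utils::read.csv(mf_path, stringsAsFactors = FALSE)
  dup <- duplicated(mf[, c("subject_id", "roi")])
  if (any(dup)) {
    stop("duplicate (subject, roi) manifest entries: ",
         paste(mf$subject_id[dup], mf$roi[dup], sep = "/",
               collapse = ", "))
  }
  out <- list()
  for (i in seq_len(nrow(mf))) {
    fp <- file.path(dir, mf$path[i])
    if (!file.exists(fp)) {
      stop("missing pattern file for subject ", mf$subject_id[i],
           ", ROI ", mf$roi[i], ": ", fp)
    }
    df <- utils::read.csv(fp, check.names = FALSE,
                          stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    dimnames(m) <- list(as.character(df[[1]]), NULL)
    out[[mf$subject_id[i]]][[mf$roi[i]]] <-
      pattern_set(m, subject_id = mf$subject_id[i], group = mf$group[i],
                  roi = mf$roi[i])
  }
  out
}

#' Write or read a full synthetic cohort
#'
#' Lays a [simulate_cohort()] result out on disk as plain text:
#' `design.csv`, `roster.csv`, `ratings.csv`, `questionnaires.csv`, the
#' `patterns/<subject>/<roi>.csv` tree with its `manifest.csv`, and the
#' serialized ground truth (`ground_truth.json`). `read_cohort()`
#' restores an equivalent object (the session-averaged table and affect
#' coordinates are recomputed from the ratings).
#'
#' @param cohort a `touch_cohort`
#' @param dir target directory
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()`
#'   a `touch_cohort`
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_design_csv(cohort$design, file.path(dir, "design.csv"))
  utils::write.csv(cohort$roster, file.path(dir, "roster.csv"),
                   row.names = FALSE)
  write_ratings_csv(cohort$ratings, file.path(dir, "ratings.csv"))
  write_questionnaires_csv(cohort$questionnaires,
                           file.path(dir, "questionnaires.csv"))
  write_patterns(cohort$patterns, file.path(dir, "patterns"))
  truth_to_json(cohort$truth, file.path(dir, "ground_truth.json"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  design <- read_design_csv(file.path(dir, "design.csv"))
  roster <- utils::read.csv(file.path(dir, "roster.csv"),
                            stringsAsFactors = FALSE)
  ratings <- read_ratings_csv(file.path(dir, "ratings.csv"))
  questionnaires <- read_questionnaires_csv(
    file.path(dir, "questionnaires.csv"))
  patterns <- read_patterns(file.path(dir, "patterns"))
  truth <- truth_from_json(file.path(dir, "ground_truth.json"))
  agg <- aggregate_sessions(ratings)
  groups <- unique(roster$group)
  affect_coords <- lapply(stats::setNames(groups, groups), function(g) {
    sub <- agg[agg$group == g, ]
    v <- tapply(sub$valence, sub$stimulus_id, mean)[design$stimulus_id]
    a <- tapply(sub$arousal, sub$stimulus_id, mean)[design$stimulus_id]
    cbind(valence = unname(v), arousal = unname(a))
  })
  structure(list(design = design, roster = roster, ratings = ratings,
                 agg = agg, affect_coords = affect_coords,
                 patterns = patterns, questionnaires = questionnaires,
                 truth = truth, config = NULL, seed = NA_integer_),
            class = "touch_cohort")
}
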