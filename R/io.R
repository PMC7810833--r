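#' Read and write the on-disk cohort formats
#'
#' All disk formats are plain text. Region ids are 0-based everywhere and
#' atlas row order is the canonical region order; every reader asserts it.
#'
#' * time series: one TSV per session, rows = time points, columns =
#'   regions, header row of region ids (`<subject>/<session>_series.tsv`)
#' * motion: whitespace-delimited, one row per volume, 6 columns
#'   (tx ty tz in mm, rx ry rz in radians) — the `rp_*.txt` convention
#' * metadata: CSV `id, age, sex, group, duration_years, n_aeds, qolie31,
#'   lsss` (clinical columns empty for controls)
#' * atlas: TSV `region_id, name, is_dmn`
#'
#' @param series,path,tr_seconds,subject_id,session_id See individual
#'   functions.
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @param series A [session_series()].
#' @export
write_session_tsv <- function(series, path) {
  d <- as.data.frame(t(series$data))
  names(d) <- as.character(seq_len(nrow(series$data)) - 1L)
  readr::write_tsv(d, path, progress = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_session_tsv <- function(path, tr_seconds, subject_id = NA_character_,
                             session_id = NA_character_) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- suppressWarnings(as.integer(names(d)))
  if (anyNA(ids) || !identical(ids, seq_along(ids) - 1L)) {
    abort(sprintf("%s: header must be the 0-based region ids in order", path))
  }
  m <- t(as.matrix(d))
  rownames(m) <- region_names(nrow(m))
  session_series(m, tr_seconds, subject_id, session_id)
}

#' @rdname cohort_io
#' @param motion T x 6 motion matrix.
#' @export
write_motion_txt <- function(motion, path) {
  utils::write.table(format(as.matrix(motion), digits = 17, trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_motion_txt <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6) {
    abort(sprintf("%s: motion file must have 6 columns, found %d",
                  path, ncol(m)))
  }
  dimnames(m) <- list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz"))
  m
}

#' @rdname cohort_io
#' @param metadata Metadata tibble.
#' @export
write_metadata_csv <- function(metadata, path) {
  readr::write_csv(metadata, path, progress = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_metadata_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         id = "c", age = "d", sex = "c", group = "c",
                         duration_years = "d", n_aeds = "i",
                         qolie31 = "d", lsss = "d"
                       ))
  if (!all(d$sex %in% c("M", "F"))) abort(sprintf("%s: sex must be M or F", path))
  if (!all(d$group %in% c("control", "patient"))) {
    abort(sprintf("%s: group must be control or patient", path))
  }
  as_tibble(d)
}

#' @rdname cohort_io
#' @param atlas Atlas tibble.
#' @export
write_atlas_tsv <- function(atlas, path) {
  readr::write_tsv(atlas[, c("region_id", "name", "is_dmn")], path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_atlas_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(region_id = "i", name = "c",
                                               is_dmn = "i"))
  if (!identical(as.integer(d$region_id), seq_len(nrow(d)) - 1L)) {
    abort(sprintf("%s: atlas rows must be the 0-based region ids in order",
                  path))
  }
  if (!all(d$is_dmn %in% c(0L, 1L))) {
    abort(sprintf("%s: is_dmn must be 0/1", path))
  }
  as_tibble(d)
}

#' Square matrix TSV with region-id header
#'
#' @param m Square numeric matrix (e.g. a Z matrix).
#' @param path File path.
#' @export
write_matrix_tsv <- function(m, path) {
  d <- as.data.frame(m)
  names(d) <- as.character(seq_len(ncol(m)) - 1L)
  readr::write_tsv(d, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) abort(sprintf("%s: matrix must be square", path))
  dimnames(m) <- NULL
  m
}

#' Matrix Market I/O for binary adjacency matrices
#'
#' @param adjacency A [binarize()] result.
#' @param path File path (`.mtx`).
#' @export
write_adjacency_mm <- function(adjacency, path) {
  Matrix::writeMM(methods::as(Matrix::Matrix(adjacency$a, sparse = TRUE),
                              "generalMatrix"), path)
  invisible(path)
}

#' @rdname write_adjacency_mm
#' @export
read_adjacency_mm <- function(path) {
  m <- as.matrix(Matrix::readMM(path))
  structure(list(a = (m != 0) * 1L, n_edges = sum(m != 0) / 2),
            class = "adjacency")
}

#' Normative model TSV serialization
#'
#' @param model A [fit_normative()] result.
#' @param path File path.
#' @export
write_model_tsv <- function(model, path) {
  readr::write_tsv(as_tibble(unclass(model)), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_model_tsv
#' @param sd_mode SD mode recorded back on the restored model.
#' @export
read_model_tsv <- function(path, sd_mode = "age_regressed") {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  structure(as_tibble(d), sd_mode = sd_mode,
            class = c("normative_model", class(as_tibble(d))))
}

#' Write a synthetic cohort to a directory
#'
#' Lays the cohort out in the exchange formats: `metadata.csv`,
#' `atlas.tsv`, one directory per subject holding
#' `ses01_series.tsv ... ` and `rp_ses01.txt ...`, and (for synthetic
#' cohorts) `ground_truth_hubs.tsv` recording the injected hub regions.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_metadata_csv(cohort$metadata, file.path(dir, "metadata.csv"))
  write_atlas_tsv(cohort$atlas, file.path(dir, "atlas.tsv"))
  hubs <- dplyr::bind_rows(lapply(cohort$subjects, function(s) {
    if (length(s$ground_truth_hubs) == 0) return(NULL)
    tibble(id = s$record$id, region_id = s$ground_truth_hubs)
  }))
  if (nrow(hubs) > 0) {
    readr::write_tsv(hubs, file.path(dir, "ground_truth_hubs.tsv"),
                     progress = FALSE)
  }
  for (s in cohort$subjects) {
    sdir <- file.path(dir, s$record$id)
    dir.create(sdir, showWarnings = FALSE)
    for (k in seq_along(s$sessions)) {
      ses <- s$sessions[[k]]
      write_session_tsv(ses, file.path(sdir, paste0(ses$session_id,
                                                    "_series.tsv")))
      write_motion_txt(s$motion[[k]],
                       file.path(sdir, paste0("rp_", ses$session_id, ".txt")))
    }
  }
  invisible(dir)
}

#' Read a cohort directory
#'
#' Inverse of [write_cohort()]. Region counts must agree between the atlas
#' and every session file; a mismatch is an error naming both files.
#'
#' @param dir Cohort directory.
#' @param tr_seconds Sampling interval of the stored series.
#' @return A `synthetic_cohort`-shaped list (`subjects`, `metadata`,
#'   `atlas`); `config` is `NULL` for cohorts read from disk.
#' @export
read_cohort <- function(dir, tr_seconds = 3) {
  metadata <- read_metadata_csv(file.path(dir, "metadata.csv"))
  atlas <- read_atlas_tsv(file.path(dir, "atlas.tsv"))
  hub_path <- file.path(dir, "ground_truth_hubs.tsv")
  hubs <- if (file.exists(hub_path)) {
    readr::read_tsv(hub_path, show_col_types = FALSE, progress = FALSE)
  } else {
    tibble(id = character(), region_id = integer())
  }
  subjects <- lapply(seq_len(nrow(metadata)), function(i) {
    id <- metadata$id[i]
    sdir <- file.path(dir, id)
    ses_files <- sort(list.files(sdir, pattern = "_series\\.tsv$"))
    sessions <- list()
    motion <- list()
    for (f in ses_files) {
      ses_id <- sub("_series\\.tsv$", "", f)
      ses <- read_session_tsv(file.path(sdir, f), tr_seconds, id, ses_id)
      if (nrow(ses$data) != nrow(atlas)) {
        abort(sprintf("region count mismatch between %s (%d) and %s (%d)",
                      file.path(sdir, f), nrow(ses$data),
                      file.path(dir, "atlas.tsv"), nrow(atlas)))
      }
      sessions[[ses_id]] <- ses
      mo_path <- file.path(sdir, paste0("rp_", ses_id, ".txt"))
      motion[ses_id] <- list(
        if (file.exists(mo_path)) read_motion_txt(mo_path) else NULL
      )
    }
    structure(
      list(record = metadata[i, ], sessions = unname(sessions),
           motion = unname(motion),
           ground_truth_hubs = as.integer(hubs$region_id[hubs$id == id])),
      class = "synthetic_subject"
    )
  })
  names(subjects) <- metadata$id
  structure(
    list(subjects = subjects, metadata = metadata, atlas = atlas,
         config = NULL),
    class = "synthetic_cohort"
  )
}
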