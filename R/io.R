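# Delimited-text I/O for matrices, subject datasets and run configs.
# Matrices are written with 17 significant digits so doubles round-trip
# exactly; headers and an index column are mandatory. Cell convention for
# connectivity matrices: (row i, col j) = influence j -> i.

#' Write a labelled numeric matrix to CSV at full precision
#'
#' @param mat numeric matrix; dimnames are used as header/index labels
#'   (defaulting to V1..Vn).
#' @param path output file path.
#' @export
write_matrix_csv <- function(mat, path) {
  mat <- as.matrix(mat)
  rn <- rownames(mat)
  cn <- colnames(mat)
  if (is.null(rn)) rn <- paste0("V", seq_len(nrow(mat)))
  if (is.null(cn)) cn <- paste0("V", seq_len(ncol(mat)))
  fmt_num <- function(x) {
    out <- sprintf("%.17g", x)
    ints <- x == floor(x) & abs(x) < 2^53
    out[ints] <- sprintf("%.0f", x[ints])
    out
  }
  lines <- c(paste(c("", cn), collapse = ","),
             vapply(seq_len(nrow(mat)), function(i)
               paste(c(rn[i], fmt_num(mat[i, ])), collapse = ","), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a labelled numeric matrix from CSV
#'
#' Expects the format written by [write_matrix_csv()]: a header row of
#' column labels and an index column of row labels. Ragged rows and
#' non-numeric cells raise errors naming the offending location.
#'
#' @param path input file path.
#' @return a numeric matrix with dimnames.
#' @export
read_matrix_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("matrix CSV needs a header and >= 1 row")
  parts <- strsplit(lines, ",", fixed = TRUE)
  ncells <- lengths(parts)
  if (any(ncells != ncells[1L]))
    stop("ragged CSV: row ", which(ncells != ncells[1L])[1L],
         " has ", ncells[ncells != ncells[1L]][1L], " cells, expected ",
         ncells[1L])
  cn <- parts[[1L]][-1L]
  rn <- vapply(parts[-1L], `[`, "", 1L)
  out <- matrix(NA_real_, length(rn), length(cn),
                dimnames = list(rn, cn))
  for (i in seq_along(rn)) {
    vals <- suppressWarnings(as.numeric(parts[[i + 1L]][-1L]))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1L]
      stop("non-numeric cell at row ", i, " (", rn[i], "), column ", bad,
           " (", cn[bad], "): '", parts[[i + 1L]][bad + 1L], "'")
    }
    out[i, ] <- vals
  }
  out
}

#' Write a synthetic dataset as per-subject CSV files
#'
#' Writes `gt.csv` plus `subject_001.csv` ... into `dir`.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_dataset_csv <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_matrix_csv(ds$ground_truth$matrix, file.path(dir, "gt.csv"))
  for (s in seq_along(ds$subjects))
    write_matrix_csv(ds$subjects[[s]],
                     file.path(dir, sprintf("subject_%03d.csv", s)))
  invisible(dir)
}

#' Read a directory of per-subject connectivity CSVs
#'
#' Reads every `*.csv` in `dir` except `gt.csv` (in lexical order) as one
#' subject matrix.
#'
#' @param dir directory of K x K CSV files.
#' @return a list of matrices suitable for [stack_subjects()].
#' @export
read_subject_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  files <- files[basename(files) != "gt.csv"]
  if (length(files) == 0L) stop("no subject CSV files in ", dir)
  lapply(files, read_matrix_csv)
}

#' Read multichannel epochs from CSV files
#'
#' Either one CSV per trial (rows = samples, columns = channels, header =
#' channel names), or a single CSV with a trial column whose values group
#' rows into trials. All trials must have the same length.
#'
#' @param paths one or more CSV paths.
#' @param fs sampling rate in Hz.
#' @param trial_col for the single-file form, the name of the trial
#'   column.
#' @return an `epochs` object (see [epochs()]).
#' @export
read_epochs_csv <- function(paths, fs, trial_col = NULL) {
  if (length(paths) == 1L && !is.null(trial_col)) {
    tab <- utils::read.csv(paths, check.names = FALSE)
    if (!trial_col %in% names(tab))
      stop("trial column '", trial_col, "' not found")
    trials <- split(tab[setdiff(names(tab), trial_col)], tab[[trial_col]])
    mats <- lapply(trials, function(d) t(as.matrix(d)))
  } else {
    mats <- lapply(paths, function(p)
      t(as.matrix(utils::read.csv(p, check.names = FALSE))))
  }
  Tn <- unique(vapply(mats, ncol, 0L))
  if (length(Tn) != 1L)
    stop("trials have unequal lengths: ", paste(Tn, collapse = ", "))
  data <- array(unlist(mats), dim = c(nrow(mats[[1L]]), Tn, length(mats)))
  dimnames(data) <- list(rownames(mats[[1L]]), NULL, NULL)
  epochs(data, fs)
}

#' Default run configuration
#'
#' All tunable parameters of the pipeline with their defaults, as a plain
#' list that round-trips losslessly through JSON.
#'
#' @param ... named overrides of the defaults.
#' @return a named list.
#' @export
run_config <- function(...) {
  cfg <- list(
    density = 0.1,
    binarize_threshold = 0.001,
    solver_tol = 1e-6,
    solver_max_iter = 500L,
    solver_n_init = 5L,
    alpha = 0.05,
    n_surrogates = 100L,
    bands = list(theta = c(3, 7), alpha = c(8, 12),
                 beta = c(13, 30), gamma = c(31, 40)),
    K = 20L, S = 10L, m = 0.1, f = 2L,
    T_iter = 100L, seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  modifyList(cfg, over)
}

#' Read / write a run configuration as JSON
#'
#' @param path JSON file path.
#' @return `read_run_config` returns the config merged over the defaults.
#' @export
read_run_config <- function(path) {
  over <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(run_config, over)
}

#' @param cfg a config list from [run_config()].
#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
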