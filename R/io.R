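fmt_num <- function(x) sprintf("%.12e", x)

#' Read a weighted connectome matrix from CSV or MatrixMarket
#'
#' CSV input is a dense headerless N x N table of comma-separated floats.
#' MatrixMarket input is the standard coordinate format (symmetric or general
#' storage both accepted). Validation (squareness, symmetry, non-negativity,
#' zero diagonal, label uniqueness) happens at load.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension: `.mtx`/`.mm` -> MatrixMarket, else
#'   CSV), `"csv"`, or `"mtx"`.
#' @param labels optional character vector of node labels, e.g. from
#'   [read_node_labels()].
#' @param fix_diagonal zero a nonzero diagonal with a warning instead of
#'   erroring.
#' @return a [weighted_connectome()].
#' @export
read_weighted_matrix <- function(path, format = c("auto", "csv", "mtx"),
                                 labels = NULL, fix_diagonal = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.(mtx|mm)$", path, ignore.case = TRUE)) "mtx"
              else "csv"
  W <- if (format == "mtx") {
    as.matrix(Matrix::readMM(path))
  } else {
    df <- tryCatch(
      utils::read.table(path, sep = ",", header = FALSE,
                        colClasses = "numeric", strip.white = TRUE),
      error = function(e) stop("malformed CSV (ragged rows or non-numeric ",
                               "entries) in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    unname(as.matrix(df))
  }
  weighted_connectome(W, labels = labels, fix_diagonal = fix_diagonal)
}

#' Read a node-label table
#'
#' Two tab-separated columns `index<TAB>label`, with an optional header line
#' `# index_base=0` or `# index_base=1` declaring the index convention
#' (default 1). Labels are returned ordered by node.
#'
#' @param path TSV file.
#' @return character vector of labels in node order.
#' @export
read_node_labels <- function(path) {
  lines <- readLines(path)
  base <- 1L
  hdr <- grep("^#", lines)
  for (h in hdr) {
    m <- regmatches(lines[h], regexec("index_base\\s*=\\s*([01])", lines[h]))[[1]]
    if (length(m) == 2) base <- as.integer(m[2])
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2))
    stop("label file must have two tab-separated columns: index<TAB>label",
         call. = FALSE)
  idx <- as.integer(vapply(parts, `[[`, "", 1)) - base + 1L
  lab <- vapply(parts, `[[`, "", 2)
  out <- character(max(idx))
  out[idx] <- lab
  if (any(!nzchar(out))) stop("label file has gaps in the node indices",
                              call. = FALSE)
  out
}

#' Write a weighted connectome to CSV + MatrixMarket + labels + manifest
#'
#' @param wc a [weighted_connectome()].
#' @param prefix output path prefix; writes `<prefix>_W.csv`,
#'   `<prefix>_W.mtx`, `<prefix>_labels.tsv` (with an `# index_base=1`
#'   header) and `<prefix>_manifest.json`.
#' @return invisibly, the vector of files written.
#' @export
write_connectome <- function(wc, prefix) {
  stopifnot(inherits(wc, "weighted_connectome"))
  f_csv <- paste0(prefix, "_W.csv")
  f_mtx <- paste0(prefix, "_W.mtx")
  f_lab <- paste0(prefix, "_labels.tsv")
  f_man <- paste0(prefix, "_manifest.json")
  utils::write.table(matrix(fmt_num(wc$W), nrow(wc$W)), f_csv, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  Matrix::writeMM(methods::as(Matrix::forceSymmetric(Matrix::Matrix(
    wc$W, sparse = TRUE)), "CsparseMatrix"), f_mtx)
  writeLines(c("# index_base=1",
               paste(seq_along(wc$labels), wc$labels, sep = "\t")), f_lab)
  manifest <- attr(wc, "manifest")
  if (is.null(manifest)) manifest <- list()
  manifest$n_nodes <- nrow(wc$W)
  manifest$index_base <- 1
  manifest$package_version <- as.character(utils::packageVersion("connectomeRD"))
  jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(f_csv, f_mtx, f_lab, f_man))
}

#' Write a trajectory, its observables and a run manifest
#'
#' Writes `<prefix>_trajectory.csv` (long format
#' `time,node_index,node_label,concentration`, or wide format with one column
#' per node when `wide = TRUE`), `<prefix>_observables.csv` (header exactly
#' `time,M,N_above`), and `<prefix>_manifest.json` echoing the full
#' configuration. All floats are serialised in scientific notation with 12
#' significant digits so re-runs can be compared byte-for-byte. Node indices
#' are written 1-based.
#'
#' @param traj a `trajectory` from [integrate_dynamics()].
#' @param series the matching data.frame from [observable_series()].
#' @param prefix output path prefix.
#' @param wide write the trajectory in wide format (one column per node).
#' @param extra optional named list merged into the manifest (e.g. input
#'   checksums, RNG seed, stopping-rule outcome).
#' @return invisibly, the vector of files written.
#' @export
write_trajectory <- function(traj, series, prefix, wide = FALSE,
                             extra = list()) {
  stopifnot(inherits(traj, "trajectory"))
  if (!isTRUE(all.equal(series$time, traj$times)))
    stop("trajectory and observable series do not share a time grid",
         call. = FALSE)
  f_tr <- paste0(prefix, "_trajectory.csv")
  f_ob <- paste0(prefix, "_observables.csv")
  f_man <- paste0(prefix, "_manifest.json")
  n <- ncol(traj$states)
  if (wide) {
    hdr <- paste(c("time", traj$labels), collapse = ",")
    rows <- vapply(seq_along(traj$times), function(i) {
      paste(c(fmt_num(traj$times[i]), fmt_num(traj$states[i, ])),
            collapse = ",")
    }, "")
    writeLines(c(hdr, rows), f_tr)
  } else {
    tlong <- rep(traj$times, each = n)
    idx <- rep(seq_len(n), times = length(traj$times))
    writeLines(c("time,node_index,node_label,concentration",
                 paste(fmt_num(tlong), idx, traj$labels[idx],
                       fmt_num(t(traj$states)), sep = ",")), f_tr)
  }
  writeLines(c("time,M,N_above",
               paste(fmt_num(series$time), fmt_num(series$M),
                     as.integer(series$N_above), sep = ",")), f_ob)
  manifest <- c(list(
    config = list(w = traj$config$w,
                  reaction = unclass(traj$config$reaction),
                  t_max = traj$config$t_max, dt = traj$config$dt,
                  method = traj$config$method,
                  euler_dt = traj$config$euler_dt,
                  clip_negative = traj$config$clip_negative,
                  rtol = traj$config$rtol, atol = traj$config$atol),
    graph = traj$graph_info,
    theta_c_used = attr(series, "theta_c"),
    index_base = 1,
    package_version = as.character(utils::packageVersion("connectomeRD")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(f_tr, f_ob, f_man))
}

#' Write the final per-node state for external viewers
#'
#' One row per node, `node_index,label,concentration` (1-based indices), for
#' colouring a brain-surface rendering in external tools.
#'
#' @param traj a `trajectory`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_final_state <- function(traj, path) {
  final <- traj$states[nrow(traj$states), ]
  writeLines(c("node_index,label,concentration",
               paste(seq_along(final), traj$labels, fmt_num(final),
                     sep = ",")), path)
  invisible(path)
}
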