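# Plain-text I/O: signals as one/two-column CSV/TSV, square matrices and
# label files as CSV, and the deterministic fixture generator. Sampling
# rates are always supplied by the caller, never inferred from files.

guess_sep <- function(path) if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","

#' Read / write a signal as delimited text
#'
#' One value per row; an optional header row carries the signal label.
#' A two-column file is read as two signals (returned as a list).
#'
#' @param path File path (`.csv` or `.tsv`).
#' @param header Does the file carry a header row (default TRUE)?
#' @return `read_signal`: numeric vector (with a `label` attribute) or a
#'   named list of two vectors for two-column files.
#' @export
read_signal <- function(path, header = TRUE) {
  d <- read.csv(path, header = header, sep = guess_sep(path))
  if (ncol(d) == 1L) {
    out <- as.numeric(d[[1L]])
    attr(out, "label") <- names(d)[1L]
    out
  } else if (ncol(d) == 2L) {
    setNames(lapply(d, as.numeric), names(d))
  } else stop("expected a one- or two-column signal file")
}

#' @rdname read_signal
#' @param x Numeric vector (or list of two) to write.
#' @param label Column header(s).
#' @param force Overwrite an existing file.
#' @export
write_signal <- function(x, path, label = "signal", force = FALSE) {
  if (file.exists(path) && !force)
    stop("refusing to overwrite ", path, " (use force = TRUE)")
  if (is.list(x)) {
    d <- as.data.frame(x)
    if (!is.null(label) && length(label) == ncol(d)) names(d) <- label
  } else {
    d <- setNames(data.frame(x), label)
  }
  write.table(d, path, sep = guess_sep(path), row.names = FALSE,
              col.names = TRUE, qmethod = "double")
  invisible(path)
}

#' Read / write a square matrix as CSV
#'
#' Connectivity and distance matrices: plain numeric CSV, optional
#' header row and row-name column detected on read.
#'
#' @param path File path.
#' @return `read_matrix_csv`: numeric matrix.
#' @export
read_matrix_csv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, ",")[[1L]][1L])))
  d <- read.csv(path, header = has_header)
  if (!is.numeric(d[[1L]])) d <- d[, -1L, drop = FALSE]
  as.matrix(sapply(d, as.numeric))
}

#' @rdname read_matrix_csv
#' @param M Matrix to write.
#' @param force Overwrite an existing file.
#' @details Missing values (e.g. pairs without a valid exponent in a
#'   per-pair exponent matrix) are written as empty cells.
#' @export
write_matrix_csv <- function(M, path, force = FALSE) {
  if (file.exists(path) && !force)
    stop("refusing to overwrite ", path, " (use force = TRUE)")
  write.table(as.matrix(M), path, sep = ",", row.names = FALSE,
              col.names = FALSE, na = "")
  invisible(path)
}

#' Read / write node labels (two-column CSV)
#'
#' Columns `node_index`, `label` - used for hemisphere membership and
#' cluster assignments of user-supplied connectomes.
#'
#' @param path File path.
#' @return `read_labels`: character vector ordered by node index.
#' @export
read_labels <- function(path) {
  d <- read.csv(path)
  stopifnot(ncol(d) >= 2L)
  as.character(d[[2L]][order(d[[1L]])])
}

#' @rdname read_labels
#' @param labels Character vector of per-node labels.
#' @param force Overwrite an existing file.
#' @export
write_labels <- function(labels, path, force = FALSE) {
  if (file.exists(path) && !force)
    stop("refusing to overwrite ", path, " (use force = TRUE)")
  write.csv(data.frame(node_index = seq_along(labels), label = labels),
            path, row.names = FALSE)
  invisible(path)
}

# Deterministic content checksum (order-sensitive byte hash).
file_checksum <- function(path) {
  b <- as.integer(readBin(path, "raw", file.info(path)$size))
  h <- 0
  for (chunk in split(b, ceiling(seq_along(b) / 4096))) {
    h <- (h * 69069 + sum(chunk * seq_along(chunk))) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Generate a deterministic fixture set
#'
#' Writes a reproducible collection of small inputs for the pipeline:
#' FARIMA surrogate pairs (3 exponents x 2 noise levels), a small Ising
#' run (48 x 48 lattice, 3 temperatures), a Kuramoto run (50
#' oscillators, 3 couplings), and a synthetic connectome with hemisphere
#' and cluster label files - plus a JSON manifest recording seeds,
#' parameters and content checksums. The same seed always yields a
#' byte-identical manifest.
#'
#' @param seed Integer root seed.
#' @param out_dir Output directory (created if absent).
#' @param n_sweeps Ising sweeps per temperature (default 8000).
#' @param force Overwrite existing files.
#' @return Path of the manifest, invisibly.
#' @export
make_fixtures <- function(seed, out_dir, n_sweeps = 8000L, force = FALSE) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for the fixture manifest")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, files = list())
  put <- function(name, params) {
    manifest$files[[name]] <<- c(params,
                                 checksum = file_checksum(file.path(out_dir, name)))
  }
  # surrogate pairs
  k <- 0L
  for (H in c(0.5, 0.75, 0.9)) {
    for (ns in c(0, 0.5)) {
      k <- k + 1L
      sp <- surrogate_pair(4096L, d = H - 0.5, noise_sigma = ns,
                           seed = child_seed(seed, k))
      nm <- sprintf("surrogate_H%02d_noise%02d.csv",
                    round(100 * H), round(10 * ns))
      write_signal(list(x1 = sp$x1, x2 = sp$x2), file.path(out_dir, nm),
                   force = force)
      put(nm, list(kind = "surrogate_pair", H = H, noise_sigma = ns,
                   n = 4096, fs = 600, omega = 1,
                   seed = child_seed(seed, k)))
    }
  }
  # Ising runs
  for (Tt in c(2.0, 2.3, 5.0)) {
    k <- k + 1L
    sim <- ising_simulate(Tt, L = 48L, n_sweeps = n_sweeps,
                          burn_in = 1000L, block = 8L,
                          seed = child_seed(seed, k))
    nm <- sprintf("ising_T%03d.csv", round(100 * Tt))
    if (file.exists(file.path(out_dir, nm)) && !force)
      stop("refusing to overwrite ", nm, " (use force = TRUE)")
    write.table(sim$series, file.path(out_dir, nm), sep = ",",
                row.names = FALSE, col.names = FALSE)
    put(nm, list(kind = "ising", temperature = Tt, L = 48, block = 8,
                 n_sweeps = n_sweeps, burn_in = 1000,
                 seed = child_seed(seed, k)))
  }
  # Kuramoto runs
  for (K in c(0, 12, 30)) {
    k <- k + 1L
    sim <- kuramoto_simulate(K, n_osc = 50L, n_steps = 4000L,
                             seed = child_seed(seed, k))
    nm <- sprintf("kuramoto_K%03d.csv", K)
    if (file.exists(file.path(out_dir, nm)) && !force)
      stop("refusing to overwrite ", nm, " (use force = TRUE)")
    write.table(sim$phases, file.path(out_dir, nm), sep = ",",
                row.names = FALSE, col.names = FALSE)
    put(nm, list(kind = "kuramoto", coupling = K, n_osc = 50,
                 n_steps = 4000, seed = child_seed(seed, k)))
  }
  # synthetic connectome + labels
  cx <- synthetic_connectome(seed = child_seed(seed, 999L))
  write_matrix_csv(cx$C, file.path(out_dir, "connectome_C.csv"), force = force)
  write_matrix_csv(cx$C_raw, file.path(out_dir, "connectome_C_raw.csv"),
                   force = force)
  write_matrix_csv(cx$L, file.path(out_dir, "connectome_L.csv"), force = force)
  write_labels(cx$hemisphere, file.path(out_dir, "connectome_hemisphere.csv"),
               force = force)
  write_labels(cx$clusters, file.path(out_dir, "connectome_clusters.csv"),
               force = force)
  for (nm in c("connectome_C.csv", "connectome_C_raw.csv", "connectome_L.csv",
               "connectome_hemisphere.csv", "connectome_clusters.csv"))
    put(nm, list(kind = "connectome", seed = child_seed(seed, 999L)))

  mpath <- file.path(out_dir, "manifest.json")
  if (file.exists(mpath) && !force)
    stop("refusing to overwrite ", mpath, " (use force = TRUE)")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}
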