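## Connectome-atlas archives: a zip file with at least two same-shaped
## square CSV matrices, `weights` (region-to-region connection strengths)
## and `tract_lengths` (inter-region fibre distances in mm, turned into
## conduction delays by dividing by a conduction speed in mm/ms).

#' Read a connectome-atlas archive
#'
#' Expects the archive to contain `weights.txt` and `tract_lengths.txt`
#' (`.csv` aliases accepted), each a plain comma- or whitespace-separated
#' N x N non-negative numeric matrix, row = source region index.
#'
#' @param archive_path path to the zip archive.
#' @param conduction_speed conduction speed in mm/ms (> 0); atlas delays
#'   are `tract_length / conduction_speed`.
#' @return an `atlas_spec` with elements `archive_path`, `weights`,
#'   `tract_lengths`, `conduction_speed`, `n_regions`.
#' @export
read_atlas <- function(archive_path, conduction_speed = 1) {
  if (!file.exists(archive_path)) {
    stop_csanet("csanet_data_error", "atlas archive not found: ",
                archive_path)
  }
  stopifnot(is.numeric(conduction_speed), conduction_speed > 0)
  exdir <- tempfile("atlas_")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  files <- utils::unzip(archive_path, exdir = exdir)
  find_member <- function(stem) {
    hit <- files[basename(files) %in% paste0(stem, c(".txt", ".csv"))]
    if (length(hit) == 0) {
      stop_csanet("csanet_data_error", "atlas archive has no ", stem,
                  ".txt/.csv member")
    }
    hit[[1]]
  }
  weights <- read_matrix_file(find_member("weights"))
  lengths <- read_matrix_file(find_member("tract_lengths"))
  if (nrow(weights) != ncol(weights)) {
    stop_csanet("csanet_data_error", "weights matrix is not square: ",
                nrow(weights), "x", ncol(weights))
  }
  if (!identical(dim(weights), dim(lengths))) {
    stop_csanet("csanet_data_error",
                "weights and tract_lengths shapes differ: ",
                paste(dim(weights), collapse = "x"), " vs ",
                paste(dim(lengths), collapse = "x"))
  }
  if (any(weights < 0) || any(lengths < 0)) {
    stop_csanet("csanet_data_error", "atlas matrices must be non-negative")
  }
  structure(list(archive_path = archive_path, weights = weights,
                 tract_lengths = lengths,
                 conduction_speed = conduction_speed,
                 n_regions = nrow(weights)),
            class = "atlas_spec")
}

## comma- or whitespace-separated numeric matrix
read_matrix_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    as.numeric(strsplit(trimws(l), "[,[:space:]]+")[[1]])
  })
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1) {
    stop_csanet("csanet_data_error", "ragged matrix in ", basename(path))
  }
  m <- do.call(rbind, rows)
  if (anyNA(m)) {
    stop_csanet("csanet_data_error", "non-numeric entries in ",
                basename(path))
  }
  m
}

load_atlas_pattern <- function(pattern) {
  stopifnot(pattern$kind == "atlas")
  read_atlas(pattern$file, conduction_speed = pattern$conduction_speed)
}

#' Generate a synthetic connectome-atlas archive
#'
#' Emulates the empirical DTI-derived archives used for whole-brain
#' region-to-region connectivity, so that no external download is ever
#' needed: `weights.txt` has a zero diagonal and a fraction `density` of
#' positive off-diagonal entries drawn log-uniformly in `[0.01, 1]`;
#' `tract_lengths.txt` is symmetric with zero diagonal and off-diagonal
#' distances uniform in `[5, 150]` mm. Identical `(n, seed, density)` give
#' a byte-identical archive (member timestamps are pinned).
#'
#' @param n number of regions (>= 2); 68 matches a standard
#'   Desikan-Killiany cortical parcellation.
#' @param seed integer seed.
#' @param density fraction of off-diagonal weights that are positive,
#'   in (0, 1].
#' @param out_path path of the zip archive to write.
#' @return `out_path`, invisibly.
#' @export
make_synthetic_atlas <- function(n, seed = 0L, density = 1,
                                 out_path = tempfile(fileext = ".zip")) {
  if (!is.numeric(n) || n < 2) {
    stop_csanet("csanet_validation_error",
                "a synthetic atlas needs n >= 2 regions")
  }
  stopifnot(density > 0, density <= 1)
  n <- as.integer(n)
  mats <- with_seed(seed, {
    w <- matrix(0, n, n)
    off <- which(row(w) != col(w))
    present <- stats::runif(length(off)) < density
    w[off[present]] <- 10^stats::runif(sum(present), log10(0.01), log10(1))
    tl <- matrix(0, n, n)
    upper <- which(upper.tri(tl))
    tl[upper] <- stats::runif(length(upper), 5, 150)
    tl <- tl + t(tl)
    list(w = w, tl = tl)
  })
  staging <- tempfile("atlas_build_")
  dir.create(staging)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  write_matrix_file(mats$w, file.path(staging, "weights.txt"))
  write_matrix_file(mats$tl, file.path(staging, "tract_lengths.txt"))
  members <- file.path(staging, c("weights.txt", "tract_lengths.txt"))
  stamp <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  Sys.setFileTime(members[1], stamp)
  Sys.setFileTime(members[2], stamp)
  out_path <- normalizePath(out_path, mustWork = FALSE)
  if (file.exists(out_path)) unlink(out_path)
  zip::zip(out_path, files = basename(members), root = staging,
           compression_level = 6, include_directories = FALSE)
  invisible(out_path)
}

write_matrix_file <- function(m, path) {
  lines <- apply(m, 1, function(r) paste(fmt_num(r), collapse = ","))
  writeLines(lines, path)
}

#' @export
print.atlas_spec <- function(x, ...) {
  cat(sprintf("<atlas_spec %d regions, %d positive weights, speed %g mm/ms>\n",
              x$n_regions, sum(x$weights > 0), x$conduction_speed))
  invisible(x)
}
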