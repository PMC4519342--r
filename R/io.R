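## PLUMED-style whitespace formats (COLVAR, HILLS), FES tables, DSSP
## strings, shift tables. All writers emit fixed-format ASCII so repeated
## runs with equal inputs are byte-identical.

fmt_num <- function(x) formatC(x, format = "g", digits = 10)

write_fields_file <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(df), collapse = " ")), con)
  if (!is.null(provenance)) writeLines(provenance, con)
  body <- do.call(paste, c(lapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col) else as.character(col)
  }), list(sep = " ")))
  writeLines(body, con)
  invisible(path)
}

read_fields_file <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#! FIELDS")) {
    abort(paste0(path, " lacks a '#! FIELDS' header"))
  }
  cols <- strsplit(sub("^#! FIELDS\\s+", "", first), "\\s+")[[1]]
  df <- readr::read_table(path, comment = "#", col_names = cols,
                          col_types = readr::cols(.default = "d"),
                          progress = FALSE)
  as_tibble(df)
}

#' Read and write COLVAR-style CV time series
#'
#' Whitespace-delimited text with a leading `#! FIELDS` header naming the
#' columns (`time`, `alpha`, `beta`, ...), the format in which biased-run
#' CV trajectories are conventionally exchanged.
#'
#' @param df Tibble of numeric columns; `path` file path.
#' @param path File path.
#' @param provenance Optional character vector of `#`-prefixed comment
#'   lines written after the header.
#' @return `read_colvar()`: a tibble; writers return `path` invisibly.
#' @export
write_colvar <- function(df, path, provenance = NULL) {
  write_fields_file(df, path, provenance)
}

#' @rdname write_colvar
#' @export
read_colvar <- function(path) read_fields_file(path)

#' @rdname write_colvar
#' @param hills A hills tibble ([hills_tibble()]).
#' @export
write_hills <- function(hills, path, provenance = NULL) {
  write_fields_file(hills, path, provenance)
}

#' @rdname write_colvar
#' @export
read_hills <- function(path) read_fields_file(path)

#' Read and write free-energy-surface tables
#'
#' Whitespace-delimited text over the FES grid, row-major: CV
#' coordinate(s), free energy in kT, and a visited flag (0/1; unvisited
#' nodes carry free energy `nan`).
#'
#' @param fes A `fes` object.
#' @param path File path.
#' @param provenance Optional comment lines.
#' @return `read_fes_table()` returns the tidy tibble form.
#' @export
write_fes_table <- function(fes, path, provenance = NULL) {
  td <- tidy(fes)
  cols <- intersect(c("alpha", "beta", "free_energy_kT", "visited"), names(td))
  out <- td[, cols]
  out$visited <- as.integer(out$visited)
  write_fields_file(out, path, provenance)
}

#' @rdname write_fes_table
#' @export
read_fes_table <- function(path) {
  out <- read_fields_file(path)
  out$visited <- out$visited > 0
  out
}

#' Read and write per-frame DSSP strings
#'
#' One line per frame holding the one-letter secondary-structure string;
#' `#`-prefixed lines are comments.
#'
#' @param ss Character vector of per-frame strings.
#' @param path File path.
#' @param provenance Optional comment lines.
#' @export
write_ss_strings <- function(ss, path, provenance = NULL) {
  writeLines(c(provenance %||% character(), ss), path)
  invisible(path)
}

#' @rdname write_ss_strings
#' @export
read_ss_strings <- function(path) {
  lines <- readLines(path)
  lines[!startsWith(lines, "#") & nzchar(lines)]
}

#' Read and write per-frame chemical-shift tables
#'
#' Predictor-style columnar text, one file per frame with columns
#' `resid resname atom shift_ppm`, plus a manifest (TSV: `file`, `frame`,
#' `time`) mapping shift files to trajectory frames. Atom-name dialects
#' are normalised on read: `H` to `HN` and `C` to `CO`.
#'
#' @param shifts Long tibble (`frame`, `resid`, `atom`, `shift_ppm`).
#' @param frames Frames tibble supplying `frame` and `time`.
#' @param dir Directory for the per-frame files and `manifest.tsv`.
#' @return `read_shift_tables()`: long shifts tibble with a `time` column.
#' @export
write_shift_tables <- function(shifts, frames, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- sort(unique(shifts$frame))
  files <- sprintf("frame_%06d.tab", ids)
  for (k in seq_along(ids)) {
    sub <- shifts[shifts$frame == ids[k], ]
    lines <- c("# resid resname atom shift_ppm",
               sprintf("%4d %3s %-2s %10.4f", sub$resid, "XXX",
                       sub$atom, sub$shift_ppm))
    writeLines(lines, file.path(dir, files[k]))
  }
  manifest <- tibble(file = files, frame = ids,
                     time = frames$time[match(ids, frames$frame)])
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"), progress = FALSE)
  invisible(dir)
}

#' @rdname write_shift_tables
#' @export
read_shift_tables <- function(dir) {
  manifest <- readr::read_tsv(file.path(dir, "manifest.tsv"),
                              col_types = "cid", progress = FALSE)
  purrr::map_dfr(seq_len(nrow(manifest)), function(k) {
    df <- readr::read_table(file.path(dir, manifest$file[k]), comment = "#",
                            col_names = c("resid", "resname", "atom",
                                          "shift_ppm"),
                            col_types = "iccd", progress = FALSE)
    df$atom <- normalize_atom_names(df$atom)
    tibble(frame = manifest$frame[k], time = manifest$time[k],
           resid = df$resid, atom = df$atom, shift_ppm = df$shift_ppm)
  })
}

#' Normalise backbone atom-name dialects
#'
#' Shift tables use either `H`/`HN` for the amide proton and `C`/`CO` for
#' the carbonyl carbon; internal names are CA, CB, HA, HN, N, CO.
#'
#' @param atom Character vector of atom names.
#' @return Normalised names.
#' @export
normalize_atom_names <- function(atom) {
  out <- toupper(atom)
  out[out == "H"] <- "HN"
  out[out == "C"] <- "CO"
  out
}

#' Read and write experimental shift tables
#'
#' CSV with columns `resid`, `atom`, `shift_ppm` and (for HN)
#' `coeff_ppb_per_K`, the format in which measured shifts plus
#' temperature coefficients enter the comparison.
#'
#' @param df Tibble with those columns.
#' @param path File path.
#' @export
write_experimental_shifts <- function(df, path) {
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_experimental_shifts
#' @export
read_experimental_shifts <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  df$atom <- normalize_atom_names(df$atom)
  as_tibble(df)
}

## ---- provenance ---------------------------------------------------------

## FNV-1a over a serialized object, as an 8-hex-digit configuration hash.
## Kept in doubles: the xor only touches the low byte, and the modular
## multiply by the FNV prime 16777619 = 2^24 + 403 is split so every
## intermediate stays below 2^53.
fnv1a_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Provenance comment block for output files
#'
#' `#`-prefixed lines recording the package version, the configuration
#' hash and the seed, embedded in every report so outputs are traceable
#' to their exact inputs. Deliberately excludes wall-clock time so equal
#' runs are byte-identical.
#'
#' @param config Configuration list.
#' @param seed Integer seed used for the run.
#' @return Character vector of comment lines.
#' @export
provenance_lines <- function(config, seed) {
  c(paste0("# generator: bemdtools ",
           as.character(utils::packageVersion("bemdtools"))),
    paste0("# config_hash: ", fnv1a_hash(config)),
    paste0("# seed: ", seed))
}
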