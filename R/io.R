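#' Read a delimited table with schema validation
#'
#' Auto-detects the delimiter (comma or tab) from the header line, then
#' validates that all required columns are present and that numeric
#' columns parse; an unparsable numeric cell is reported with its row
#' number.
#'
#' @param path file path.
#' @param schema named character vector mapping required column names to
#'   types (`"numeric"` or `"character"`), e.g.
#'   `c(peg_percent = "numeric", od = "numeric")`.
#' @return data frame with validated (and type-converted) columns.
#' @export
read_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", comment.char = "")
  if (!is.null(schema)) {
    missing <- setdiff(names(schema), names(df))
    if (length(missing)) {
      stop("missing required column(s): ", paste(missing, collapse = ", "))
    }
    for (col in names(schema)) {
      if (schema[[col]] == "numeric") {
        vals <- suppressWarnings(as.numeric(df[[col]]))
        bad <- which(is.na(vals) & !(df[[col]] %in% c("NA", "")))
        if (length(bad)) {
          stop(sprintf("column '%s': unparsable numeric value '%s' at row %d",
                       col, df[[col]][bad[1]], bad[1]))
        }
        df[[col]] <- vals
      }
    }
  } else {
    # best-effort numeric conversion
    for (col in names(df)) {
      vals <- suppressWarnings(as.numeric(df[[col]]))
      if (!anyNA(vals)) df[[col]] <- vals
    }
  }
  df
}

#' Write a delimited table
#'
#' @param df data frame.
#' @param path output path; extension `.tsv` selects tab, otherwise
#'   comma.
#' @export
write_table <- function(df, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a trajectory as extended XYZ
#'
#' One block per frame: particle count, a comment line carrying
#' `time=... box_edge=... phi=... sigma_nm=...`, then one row per
#' particle with species label, coordinates and diameter, written at
#' full precision (17 significant digits) so a read/write cycle
#' round-trips exactly.
#'
#' @param traj an `hs_traj`.
#' @param path output path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "hs_traj"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(traj$species)
  labels <- traj$species_names[traj$species]
  for (fr in traj$frames) {
    writeLines(as.character(n), con)
    writeLines(sprintf("time=%.17g box_edge=%.17g phi=%.17g sigma_nm=%.17g",
                       fr$time, traj$box_edge, traj$phi, traj$sigma_nm), con)
    writeLines(sprintf("%s %.17g %.17g %.17g %.17g", labels,
                       fr$positions[, 1], fr$positions[, 2],
                       fr$positions[, 3], traj$diameters), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory written by [write_trajectory()]
#'
#' @param path input path.
#' @return an `hs_traj`.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  frames <- list()
  meta <- NULL
  species_lab <- NULL
  diam <- NULL
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n)) stop("malformed frame header at line ", i)
    if (i + 1 + n > length(lines) + 1) stop("truncated frame at line ", i)
    comment <- lines[i + 1]
    kv <- regmatches(comment, gregexpr("[A-Za-z_]+=[^ ]+", comment))[[1]]
    meta <- stats::setNames(
      as.numeric(sub("^[A-Za-z_]+=", "", kv)),
      sub("=.*$", "", kv))
    body <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(body, " +")
    lab <- vapply(parts, `[[`, character(1), 1)
    num <- t(vapply(parts, function(p) as.numeric(p[2:5]), numeric(4)))
    if (is.null(species_lab)) {
      species_lab <- lab
      diam <- num[, 4]
    }
    frames[[length(frames) + 1]] <- list(positions = num[, 1:3, drop = FALSE],
                                         time = unname(meta["time"]))
    i <- i + 2 + n
  }
  if (!length(frames)) {
    return(structure(list(frames = list(), species = integer(0),
                          species_names = character(0),
                          diameters = numeric(0), box_edge = NA_real_,
                          sigma_nm = NA_real_, phi = NA_real_),
                     class = "hs_traj"))
  }
  nm <- unique(species_lab)
  structure(list(frames = frames,
                 species = match(species_lab, nm),
                 species_names = nm,
                 diameters = diam,
                 box_edge = unname(meta["box_edge"]),
                 sigma_nm = unname(meta["sigma_nm"]),
                 phi = unname(meta["phi"])),
            class = "hs_traj")
}

#' Write a run manifest next to outputs
#'
#' Every CLI run drops a `manifest.txt` (config echo, package version,
#' seed, timestamp) beside its outputs so any result directory is
#' reproducible on its own.
#'
#' @param out_dir output directory.
#' @param config named list echoed into the manifest.
#' @export
write_manifest <- function(out_dir, config) {
  lines <- c(sprintf("package=lenscrowd %s",
                     as.character(utils::packageVersion("lenscrowd"))),
             sprintf("date=%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             vapply(names(config), function(k) {
               sprintf("%s=%s", k, paste(format(config[[k]]), collapse = ","))
             }, character(1)))
  writeLines(lines, file.path(out_dir, "manifest.txt"))
  invisible(file.path(out_dir, "manifest.txt"))
}
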