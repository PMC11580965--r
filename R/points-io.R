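#' Build a particle measure from a table of detections
#'
#' One particle per detection row, with unit weight (optionally scaled by a
#' section-thickness factor) and a one-hot feature distribution on the row's
#' label.  Duplicate coordinates are allowed: detections are counts, not
#' samples.
#'
#' @param points Data frame with numeric columns `x`, `y`, `z` (micrometers;
#'   `z` may be omitted for planar data) and a character/factor column
#'   `feature`.
#' @param feature_space A [feature_space()] containing every label present.
#' @param section_weight Scalar (or per-row vector) mass per detection;
#'   defaults to 1.  Set to the section thickness to weight serial sections
#'   by the tissue slab they represent.
#' @return A `particle_measure` with one particle per row.
#' @export
empirical_measure_from_points <- function(points, feature_space,
                                          section_weight = 1) {
  points <- as.data.frame(points)
  if (nrow(points) == 0L) return(empty_measure(feature_space))
  need <- c("x", "y", "feature")
  if (!all(need %in% names(points)))
    stop("'points' needs columns x, y (optionally z) and feature")
  z <- if ("z" %in% names(points)) points$z else 0
  lab <- as.character(points$feature)
  unknown <- setdiff(unique(lab), feature_space$labels)
  if (length(unknown))
    stop("labels not in the feature space: ", paste(unknown, collapse = ", "))
  idx <- match(lab, feature_space$labels)
  nf <- length(feature_space$labels)
  probs <- matrix(0, nrow(points), nf)
  probs[cbind(seq_len(nrow(points)), idx)] <- 1
  particle_measure(cbind(points$x, points$y, z),
                   rep_len(section_weight, nrow(points)), probs, feature_space)
}

#' Read a point table from CSV
#'
#' Expects header columns `x,y,z,feature` (`z` optional); extra columns are
#' preserved in the returned data frame and ignored by the core.
#'
#' @param path CSV file path.
#' @return Data frame of detections.
#' @export
read_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "feature")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("point table ", path, " is missing columns: ", paste(miss, collapse = ", "))
  for (cl in intersect(c("x", "y", "z"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (length(bad))
      stop(sprintf("non-numeric '%s' value at data line %d of %s", cl, bad[1], path))
    if (anyNA(v))
      stop(sprintf("missing '%s' value at data line %d of %s", cl, which(is.na(v))[1], path))
    df[[cl]] <- v
  }
  df
}

#' Write a point table to CSV
#' @param points Data frame with columns `x,y,z,feature` (extra columns kept).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_points <- function(points, path) {
  utils::write.csv(as.data.frame(points), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a particle measure to a text container
#'
#' A plain-text format: '#'-prefixed YAML metadata lines (units, feature
#' labels, provenance) followed by a CSV body with columns
#' `x,y,z,w,p_<label>...`.
#'
#' @param mu A `particle_measure`.
#' @param path Output file path.
#' @param units Coordinate units recorded in the metadata (default `"um"`).
#' @return `path`, invisibly.
#' @export
write_measure <- function(mu, path, units = "um") {
  meta <- list(format = "varimap-measure", version = 1L, units = units,
               kind = mu$feature_space$kind, labels = mu$feature_space$labels)
  if (!is.null(mu$feature_space$values)) meta$values <- mu$feature_space$values
  hdr <- paste0("# ", strsplit(yaml::as.yaml(meta), "\n")[[1]])
  body <- data.frame(x = mu$positions[, 1], y = mu$positions[, 2],
                     z = mu$positions[, 3], w = mu$weights)
  pm <- as.data.frame(mu$feature_probs)
  names(pm) <- paste0("p_", mu$feature_space$labels)
  body <- cbind(body, pm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(body, con, row.names = FALSE)
  invisible(path)
}

#' Read a particle measure written by [write_measure()]
#' @param path File path.
#' @return A `particle_measure`.
#' @export
read_measure <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "# ")
  meta <- yaml::yaml.load(paste(sub("^# ", "", lines[is_meta]), collapse = "\n"))
  if (is.null(meta$format) || meta$format != "varimap-measure")
    stop(path, " is not a varimap measure file")
  fs <- feature_space(meta$labels, kind = meta$kind,
                      values = if (!is.null(meta$values)) as.numeric(meta$values))
  body <- utils::read.csv(textConnection(lines[!is_meta]))
  pcols <- paste0("p_", fs$labels)
  miss <- setdiff(pcols, names(body))
  if (length(miss)) stop("measure file is missing columns: ", paste(miss, collapse = ", "))
  particle_measure(cbind(body$x, body$y, body$z), body$w,
                   as.matrix(body[, pcols, drop = FALSE]), fs)
}
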