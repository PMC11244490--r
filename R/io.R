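#' Read a point cloud from disk
#'
#' Two formats are supported: whitespace-separated XYZ text (three numeric
#' columns, no header) and LAS 1.x with point record format 0 (the writer's
#' own output and any standard-conforming producer). LAS integer coordinates
#' are rescaled with the header scale/offset; the classification byte, the
#' user-data byte (source tag: 1 = als, 2 = tls) and the point-source-id
#' field (segment label) are restored to columns when present.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"xyz"` or `"las"`.
#' @param frame coordinate frame label to attach.
#' @return a `bamboo_cloud`.
#' @export
read_point_cloud <- function(path, format = c("auto", "xyz", "las"),
                             frame = c("projected", "local")) {
  format <- match.arg(format)
  frame <- match.arg(frame)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.las$", path, ignore.case = TRUE)) "las" else "xyz"
  }
  if (format == "xyz") read_xyz(path, frame) else read_las(path, frame)
}

read_xyz <- function(path, frame) {
  if (file.size(path) == 0) {
    warn(paste0("empty point-cloud file: ", path))
    return(point_cloud(NULL, frame = frame))
  }
  df <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = "numeric"),
    error = function(e) abort(paste0("malformed XYZ file '", path, "': ",
                                     conditionMessage(e)))
  )
  if (ncol(df) < 3) {
    abort(paste0("XYZ file '", path, "' has ", ncol(df),
                 " columns; need x y z"))
  }
  names(df)[1:3] <- c("x", "y", "z")
  m <- as.matrix(df[, 1:3])
  if (!all(is.finite(m))) {
    bad <- which(rowSums(!is.finite(m)) > 0)[1]
    abort(paste0("non-finite coordinate in '", path, "' at line ", bad))
  }
  point_cloud(df[, 1:3], frame = frame)
}

#' Write a point cloud to disk
#'
#' XYZ text stores coordinates at fixed decimal precision (`digits`); LAS
#' stores quantized coordinates at the given scale and carries the
#' classification code, the source tag and the segment label so a
#' segmentation survives a round trip.
#'
#' @param cloud a `bamboo_cloud`.
#' @param path output path.
#' @param format `"auto"`, `"xyz"` or `"las"`.
#' @param digits decimal places for XYZ text.
#' @param scale LAS quantization step (m).
#' @return the path, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = c("auto", "xyz", "las"),
                              digits = 4, scale = 0.001) {
  cloud <- as_point_cloud(cloud)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.las$", path, ignore.case = TRUE)) "las" else "xyz"
  }
  if (format == "xyz") {
    m <- coords_matrix(cloud)
    lines <- sprintf(paste0("%.", digits, "f %.", digits, "f %.", digits, "f"),
                     m[, 1], m[, 2], m[, 3])
    writeLines(lines, path)
  } else {
    write_las(cloud, path, scale)
  }
  invisible(path)
}

# --- minimal LAS 1.2, point data record format 0 -------------------------
# No LAS reader exists in this R environment, so the subset of the format
# the pipeline needs is implemented directly: 227-byte header, PDRF 0
# records (x/y/z int32 + intensity + flags + classification + scan angle +
# user data + point source id). Little-endian, as the format prescribes.

write_las <- function(cloud, path, scale = 0.001) {
  m <- coords_matrix(cloud)
  n <- nrow(m)
  off <- if (n > 0) floor(apply(m, 2, min)) else c(0, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  writeChar("LASF", con, 4, eos = NULL)
  wb(0L, 2); wb(0L, 2)                      # file source id, global encoding
  writeBin(raw(16), con)                    # project GUID
  writeBin(as.raw(c(1, 2)), con)            # version 1.2
  writeChar(formatC("bamboostand", width = 32, flag = "-"), con, 32, eos = NULL)
  writeChar(formatC("bamboostand", width = 32, flag = "-"), con, 32, eos = NULL)
  wb(1L, 2); wb(2026L, 2)                   # day / year
  wb(227L, 2)                               # header size
  wb(227L, 4)                               # offset to point data
  wb(0L, 4)                                 # number of VLRs
  writeBin(as.raw(0), con)                  # point data record format 0
  wb(20L, 2)                                # record length
  wb(n, 4)                                  # number of points
  wb(rep(c(n, 0L, 0L, 0L, 0L), 1), 4)       # points by return
  writeBin(rep(scale, 3), con, endian = "little")         # x/y/z scale
  writeBin(as.numeric(off), con, endian = "little")       # x/y/z offset
  rng <- function(v) if (n > 0) c(max(v), min(v)) else c(0, 0)
  writeBin(c(rng(m[, 1]), rng(m[, 2]), rng(m[, 3])), con, endian = "little")

  if (n > 0) {
    xi <- as.integer(round((m[, 1] - off[1]) / scale))
    yi <- as.integer(round((m[, 2] - off[2]) / scale))
    zi <- as.integer(round((m[, 3] - off[3]) / scale))
    cls <- if ("classification" %in% names(cloud)) {
      as.integer(cloud$classification)
    } else rep(0L, n)
    src <- if ("source" %in% names(cloud)) {
      match(as.character(cloud$source), c("als", "tls"))
    } else rep(NA_integer_, n)
    src[is.na(src)] <- 0L
    seg <- if ("segment_id" %in% names(cloud)) {
      ifelse(is.na(cloud$segment_id), 0L, as.integer(cloud$segment_id))
    } else rep(0L, n)
    # assemble all records in one raw matrix (rows = bytes of one record)
    rec <- matrix(as.raw(0), nrow = 20, ncol = n)
    rec[1:4, ]   <- matrix(writeBin(xi, raw(), size = 4, endian = "little"), 4)
    rec[5:8, ]   <- matrix(writeBin(yi, raw(), size = 4, endian = "little"), 4)
    rec[9:12, ]  <- matrix(writeBin(zi, raw(), size = 4, endian = "little"), 4)
    rec[15, ]    <- as.raw(0x09)                     # return 1 of 1
    rec[16, ]    <- as.raw(cls %% 256L)
    rec[18, ]    <- as.raw(src %% 256L)
    rec[19:20, ] <- matrix(writeBin(as.integer(seg %% 65536L), raw(),
                                    size = 2, endian = "little"), 2)
    writeBin(as.vector(rec), con)
  }
  invisible(path)
}

read_las <- function(path, frame) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4, useBytes = TRUE)
  if (!identical(sig, "LASF")) {
    abort(paste0("'", path, "' is not a LAS file (bad signature)"))
  }
  seek(con, 24)
  ver <- readBin(con, "integer", 2, size = 1, signed = FALSE)
  seek(con, 94)
  header_size <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                         endian = "little")
  offset_data <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "integer", 1, size = 4, endian = "little") # n VLRs
  pdrf <- as.integer(readBin(con, "raw", 1))
  rec_len <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                     endian = "little")
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  seek(con, 131)
  sc <- readBin(con, "numeric", 3, endian = "little")
  of <- readBin(con, "numeric", 3, endian = "little")
  if (pdrf > 5) abort(paste0("unsupported LAS point format ", pdrf))
  if (n == 0) {
    warn(paste0("empty point-cloud file: ", path))
    return(point_cloud(NULL, frame = frame))
  }
  seek(con, offset_data)
  body <- readBin(con, "raw", n * rec_len)
  if (length(body) < n * rec_len) {
    abort(paste0("truncated LAS file '", path, "': expected ", n,
                 " records of ", rec_len, " bytes"))
  }
  rec <- matrix(body, nrow = rec_len)
  int4 <- function(rows) {
    readBin(as.vector(rec[rows, ]), "integer", n, size = 4, endian = "little")
  }
  x <- int4(1:4) * sc[1] + of[1]
  y <- int4(5:8) * sc[2] + of[2]
  z <- int4(9:12) * sc[3] + of[3]
  cls <- as.integer(rec[16, ])
  usr <- as.integer(rec[18, ])
  psid <- readBin(as.vector(rec[19:20, ]), "integer", n, size = 2,
                  signed = FALSE, endian = "little")
  df <- tibble::tibble(x = x, y = y, z = z, classification = cls)
  if (any(usr %in% 1:2)) {
    df$source <- c("als", "tls", NA_character_)[ifelse(usr %in% 1:2, usr, 3L)]
  }
  if (any(psid > 0)) df$segment_id <- ifelse(psid > 0, psid, NA_integer_)
  point_cloud(df, frame = frame)
}

# --- tabular interchange --------------------------------------------------

#' Read surveyed control points
#'
#' CSV with columns `target_id`, `local_x`, `local_y`, `local_z`, `proj_x`,
#' `proj_y`, `proj_z`: one row per corner target pairing its coordinates in
#' the scanner-local and the projected frame.
#'
#' @param path CSV path.
#' @return validated control-point tibble.
#' @export
read_control_points <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_control_points(df)
}

validate_control_points <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("target_id", "local_x", "local_y", "local_z",
            "proj_x", "proj_y", "proj_z")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("control-point table missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(df) < 3) {
    abort(paste0("need at least 3 control pairs for the 7-parameter ",
                 "transform; got ", nrow(df)))
  }
  if (anyDuplicated(df$target_id)) {
    abort(paste0("duplicate target id(s): ",
                 paste(unique(df$target_id[duplicated(df$target_id)]),
                       collapse = ", ")))
  }
  m <- as.matrix(df[, setdiff(need, "target_id")])
  if (!all(is.finite(m))) abort("control-point coordinates must be finite")
  df
}

#' @rdname read_control_points
#' @param control control-point tibble.
#' @export
write_control_points <- function(control, path) {
  readr::write_csv(validate_control_points(control), path)
  invisible(path)
}

#' Read a reference field inventory
#'
#' CSV with one surveyed plant per row: `plant_id`, `x`, `y` (projected
#' metres) and optionally `dbh_m`, `height_m`.
#'
#' @param path CSV path.
#' @return validated inventory tibble.
#' @export
read_inventory <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_inventory(df)
}

validate_inventory <- function(df) {
  df <- tibble::as_tibble(df)
  miss <- setdiff(c("plant_id", "x", "y"), names(df))
  if (length(miss) > 0) {
    abort(paste0("inventory missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!all(is.finite(df$x)) || !all(is.finite(df$y))) {
    abort("inventory positions must be finite")
  }
  for (col in intersect(c("dbh_m", "height_m"), names(df))) {
    v <- df[[col]]
    if (any(!is.na(v) & v <= 0)) abort(paste0(col, " must be > 0"))
  }
  df
}

#' @rdname read_inventory
#' @param inventory inventory tibble.
#' @export
write_inventory <- function(inventory, path) {
  readr::write_csv(validate_inventory(inventory), path)
  invisible(path)
}
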