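#' Write a frame sequence to a directory of image files
#'
#' Frames are written as zero-padded numbered 8-bit grayscale images
#' (`frame_00001.pgm`, ...). PGM output uses binary `P5` by default; set
#' `ascii = TRUE` for plain-text `P2`, handy for small committed fixtures.
#'
#' @param frames a `frame_sequence`.
#' @param dir output directory (created if missing).
#' @param format `"pgm"` or `"png"`.
#' @param ascii write plain `P2` PGM instead of binary `P5`.
#' @return `dir`, invisibly.
#' @export
write_frames <- function(frames, dir, format = c("pgm", "png"), ascii = FALSE) {
  stopifnot(inherits(frames, "frame_sequence"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(frames$frames)
  for (i in seq_len(n)) {
    path <- file.path(dir, sprintf("frame_%05d.%s", i, format))
    f <- round(frames$frames[[i]])
    f[f < 0] <- 0; f[f > 255] <- 255
    if (format == "pgm") write_pgm(f, path, ascii = ascii)
    else png::writePNG(f / 255, path)
  }
  writeLines(sprintf("interval_ms = %g", frames$interval),
             file.path(dir, "sequence.cfg"))
  invisible(dir)
}

#' Read a directory of numbered grayscale frames
#'
#' Accepts the layout written by [write_frames()]: files ordered by their
#' zero-padded numeric names, a single extension (`.pgm` or `.png`) per
#' directory, with an optional `sequence.cfg` carrying `interval_ms`.
#'
#' @param dir directory of frames.
#' @param interval frame interval in ms; overrides any `sequence.cfg`.
#' @return a `frame_sequence` with luminance on the 0--255 scale.
#' @export
read_frames <- function(dir, interval = NULL) {
  files <- list.files(dir, pattern = "\\.(pgm|png)$", full.names = TRUE)
  if (length(files) == 0) stop("no .pgm or .png frames found in ", dir)
  ext <- unique(tolower(sub(".*\\.", "", files)))
  if (length(ext) > 1) stop("mixed frame extensions in ", dir, ": ",
                            paste(ext, collapse = ", "))
  files <- files[order(basename(files))]
  frames <- lapply(files, function(p) {
    if (ext == "pgm") read_pgm(p)
    else to_grayscale(png::readPNG(p) * 255)$values
  })
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frame shape changes mid-sequence in ", dir)
  if (is.null(interval)) {
    cfg <- file.path(dir, "sequence.cfg")
    interval <- 30
    if (file.exists(cfg)) {
      kv <- parse_kv_file(cfg)
      if (!is.null(kv$interval_ms)) interval <- as.numeric(kv$interval_ms)
    }
  }
  structure(list(frames = frames, interval = interval,
                 resolution = dim(frames[[1]])),
            class = "frame_sequence")
}

#' Write a matrix as an 8-bit PGM image
#'
#' @param mat numeric matrix with values in `[0, 255]`.
#' @param path output file.
#' @param ascii write plain-text `P2` instead of binary `P5`.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(mat, path, ascii = FALSE) {
  v <- as.integer(round(t(mat)))            # row-major pixel order
  if (any(v < 0 | v > 255)) stop("PGM pixels must lie in [0, 255]")
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(mat), nrow(mat)), "255"), con)
    writeLines(paste(v, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(mat), nrow(mat)), con,
              eos = NULL)
    writeBin(as.raw(v), con)
  }
  invisible(path)
}

#' Read an 8-bit PGM image (P2 or P5)
#'
#' @param path file path.
#' @return numeric matrix of luminance values.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # header: magic, width, height, maxval; '#' comments allowed
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0 || ch == "") stop("truncated PGM header in ", path)
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (length(ch) == 0 || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok) else next
      }
      tok <- paste0(tok, ch)
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) stop("not a P2/P5 PGM file: ", path)
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (maxval > 255) stop("only 8-bit PGM supported")
  n <- w * h
  v <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n))
  } else {
    as.integer(scan(con, what = integer(), n = n, quiet = TRUE))
  }
  if (length(v) != n) stop("truncated PGM pixel data in ", path)
  matrix(v, nrow = h, ncol = w, byrow = TRUE)
}

# Parse a flat "key = value" text file ('#' comments, blank lines allowed).
parse_kv_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("unparseable config line (expected 'key = value'): ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!nzchar(key)) stop("empty key in config line: ", ln)
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
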