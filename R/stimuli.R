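#' Binary input pattern on the 28x28 retina
#'
#' @param grid 28x28 logical matrix (`TRUE` = active pixel / PRE spike).
#' @param label Character label.
#' @return An object of class `retina_pattern` with fields `grid`, `label`
#'   and `n_active`.
#' @export
retina_pattern <- function(grid, label = "") {
  stopifnot(is.matrix(grid), is.logical(grid))
  structure(list(grid = grid, label = label, n_active = sum(grid)),
            class = "retina_pattern")
}

#' @export
print.retina_pattern <- function(x, ...) {
  cat(sprintf("retina pattern \"%s\": %dx%d, %d active pixels\n",
              x$label, nrow(x$grid), ncol(x$grid), x$n_active))
  invisible(x)
}

#' Active PRE indices of a pattern
#'
#' Column-major linear indices of the active pixels; these are the PRE
#' neuron indices used by the network engine.
#'
#' @param pattern A [retina_pattern()].
#' @return Integer vector of active PRE indices.
#' @export
pattern_active <- function(pattern) which(pattern$grid)

.set_cells <- function(grid, rows, cols) {
  for (r in rows) grid[r, cols] <- TRUE
  grid
}

#' Deterministic digit-like stimulus fixtures
#'
#' Programmatic binary bitmaps of the digits "1", "2" and "3" on the
#' 28x28 retina, used as stand-ins for handwritten digits so that every
#' simulation is self-contained. The "1" fixture has exactly 76 active
#' pixels (hence 708 background pixels), matching the pattern/background
#' split used throughout the single-pattern learning experiments.
#'
#' @return A named list of [retina_pattern()] objects (`"1"`, `"2"`, `"3"`).
#' @examples
#' digs <- make_fixture_digits()
#' digs[["1"]]$n_active  # 76
#' @export
make_fixture_digits <- function() {
  g1 <- matrix(FALSE, 28, 28)
  g1 <- .set_cells(g1, 5:24, 13:15)            # main stroke
  for (rc in list(c(6, 12), c(7, 11), c(7, 12),
                  c(8, 10), c(8, 11), c(9, 10)))
    g1[rc[1], rc[2]] <- TRUE                   # flag
  g1 <- .set_cells(g1, 24, c(10:12, 16:18))    # base serif
  g1 <- .set_cells(g1, 23, c(11, 12, 16, 17))

  g2 <- matrix(FALSE, 28, 28)
  g2 <- .set_cells(g2, 6, 11:17)
  g2 <- .set_cells(g2, 7, 10:18)
  g2 <- .set_cells(g2, 8:10, 16:18)
  g2 <- .set_cells(g2, 11, 15:17)
  g2 <- .set_cells(g2, 12, 14:16)
  g2 <- .set_cells(g2, 13, 13:15)
  g2 <- .set_cells(g2, 14, 12:14)
  g2 <- .set_cells(g2, 15, 11:13)
  g2 <- .set_cells(g2, 16, 10:12)
  g2 <- .set_cells(g2, 18:19, 10:18)

  g3 <- matrix(FALSE, 28, 28)
  g3 <- .set_cells(g3, 6, 10:17)
  g3 <- .set_cells(g3, 7, 10:18)
  g3 <- .set_cells(g3, 8:9, 16:18)
  g3 <- .set_cells(g3, 10, 13:17)
  g3 <- .set_cells(g3, 11, 13:16)
  g3 <- .set_cells(g3, 12:16, 16:18)
  g3 <- .set_cells(g3, 17, 10:18)
  g3 <- .set_cells(g3, 18, 10:17)

  list("1" = retina_pattern(g1, "1"),
       "2" = retina_pattern(g2, "2"),
       "3" = retina_pattern(g3, "3"))
}

#' Presentation schedule for pattern and noise epochs
#'
#' Each epoch presents either one of the listed patterns (with its stated
#' probability) or an instance of white 1/0 noise (with the remaining
#' probability). Noise activates each PRE independently with probability
#' `noise_density` (`mode = "bernoulli"`), or a fixed count
#' `round(noise_density * N)` of distinct PREs (`mode = "fixed"`).
#'
#' @param patterns List of [retina_pattern()] objects (may be empty).
#' @param pattern_probs Numeric vector of per-pattern presentation
#'   probabilities; their sum must be at most 1, the remainder is noise.
#' @param noise_density Expected fraction of PREs active in a noise epoch.
#' @param mode Noise sampling mode, `"bernoulli"` or `"fixed"`.
#' @return An object of class `epoch_schedule`.
#' @export
make_schedule <- function(patterns, pattern_probs, noise_density,
                          mode = c("bernoulli", "fixed")) {
  mode <- match.arg(mode)
  stopifnot(length(patterns) == length(pattern_probs),
            all(pattern_probs >= 0), sum(pattern_probs) <= 1 + 1e-12,
            noise_density >= 0, noise_density <= 1)
  structure(list(patterns = patterns, pattern_probs = pattern_probs,
                 noise_prob = max(0, 1 - sum(pattern_probs)),
                 noise_density = noise_density, mode = mode),
            class = "epoch_schedule")
}

#' Draw one epoch input from a schedule
#'
#' Uses the current R random number generator state; seed the session (or
#' the enclosing experiment runner) for reproducibility.
#'
#' @param schedule An [make_schedule()] object.
#' @param N Number of PRE neurons.
#' @return A list with `kind` (`"pattern"` or `"noise"`), `label`, and
#'   `active` (integer PRE indices).
#' @export
sample_epoch <- function(schedule, N = 784) {
  k <- length(schedule$patterns)
  u <- stats::runif(1)
  cum <- cumsum(schedule$pattern_probs)
  idx <- if (k > 0) which(u <= cum)[1] else NA_integer_
  if (!is.na(idx)) {
    p <- schedule$patterns[[idx]]
    return(list(kind = "pattern", label = p$label,
                active = pattern_active(p)))
  }
  active <- if (schedule$mode == "bernoulli") {
    which(stats::runif(N) < schedule$noise_density)
  } else {
    n <- round(schedule$noise_density * N)
    sort(sample.int(N, min(n, N)))
  }
  list(kind = "noise", label = "noise", active = active)
}

# ---- readers / writers --------------------------------------------------

.read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header tokens (magic, width, height, maxval), '#' comments allowed
  tokens <- character(0)
  buf <- character(0)
  while (length(tokens) < 4) {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (length(ch) == 0) stop("truncated PGM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (length(ch) == 0 || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[ \t\r\n]", ch)) {
      if (nzchar(paste(buf, collapse = ""))) {
        tokens <- c(tokens, paste(buf, collapse = ""))
        buf <- character(0)
      }
    } else buf <- c(buf, ch)
  }
  magic <- tokens[1]
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  n <- w * h
  vals <- if (magic == "P2") {
    rest <- readChar(con, file.size(path), useBytes = TRUE)
    as.integer(strsplit(trimws(rest), "[ \t\r\n]+")[[1]])[seq_len(n)]
  } else if (magic == "P5") {
    as.integer(readBin(con, "raw", n))
  } else stop("unsupported PGM magic: ", magic)
  if (length(vals) < n || anyNA(vals)) stop("truncated PGM data")
  list(mat = matrix(vals, nrow = h, ncol = w, byrow = TRUE),
       maxval = maxval)
}

.read_idx_image <- function(path, index) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (magic != 2051L) stop("not an IDX image file (magic != 2051)")
  dims <- readBin(con, "integer", 3, size = 4, endian = "big")
  n <- dims[1]; h <- dims[2]; w <- dims[3]
  if (index < 1 || index > n) stop("IDX image index out of range")
  seek(con, 16 + (index - 1) * h * w)
  vals <- as.integer(readBin(con, "raw", h * w))
  list(mat = matrix(vals, nrow = h, ncol = w, byrow = TRUE), maxval = 255L)
}

#' Load a binary pattern from a bitmap file
#'
#' Reads a 28x28 bitmap from a PGM (P2 ASCII or P5 binary), a headerless
#' CSV grid, or an IDX image file (the container format of the MNIST
#' distribution), and binarizes it at `threshold` (a fraction of the
#' format's maximum gray value). Inputs that are not 28x28 are rejected;
#' an all-zero pattern is accepted with a warning.
#'
#' @param path File path.
#' @param format `"pgm"`, `"csv"`, `"idx"`, or `"auto"` (by extension).
#' @param threshold Binarization threshold as a fraction of the maximum
#'   gray value.
#' @param index For IDX files, which image to extract (1-based).
#' @param label Label for the resulting pattern (defaults to the file
#'   name).
#' @return A [retina_pattern()].
#' @export
load_pattern <- function(path, format = c("auto", "pgm", "csv", "idx"),
                         threshold = 0.5, index = 1,
                         label = basename(path)) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pgm = "pgm", csv = "csv",
                     idx = "idx", "idx3-ubyte" = "idx", ubyte = "idx",
                     stop("cannot infer format from extension: ", ext))
  }
  img <- switch(format,
    pgm = .read_pgm(path),
    csv = {
      m <- as.matrix(utils::read.csv(path, header = FALSE))
      storage.mode(m) <- "double"
      dimnames(m) <- NULL
      list(mat = m, maxval = max(1, max(m)))
    },
    idx = .read_idx_image(path, index))
  if (!all(dim(img$mat) == c(28, 28)))
    stop(sprintf("expected a 28x28 bitmap, got %dx%d",
                 nrow(img$mat), ncol(img$mat)))
  grid <- img$mat / img$maxval > threshold
  if (!any(grid)) warning("loaded pattern has no active pixels")
  retina_pattern(grid, label)
}

#' Write a pattern to a plain-text bitmap
#'
#' Writers for the round-trippable plain-text formats: PGM P2 (ASCII,
#' maxval 255) and headerless CSV of 0/1.
#'
#' @param pattern A [retina_pattern()].
#' @param path Output file path.
#' @param format `"pgm"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_pattern <- function(pattern, path, format = c("pgm", "csv")) {
  format <- match.arg(format)
  g <- pattern$grid
  if (format == "pgm") {
    lines <- c("P2", paste(ncol(g), nrow(g)), "255",
               apply(ifelse(g, 255L, 0L), 1, paste, collapse = " "))
    writeLines(lines, path)
  } else {
    utils::write.table(ifelse(g, 1L, 0L), path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
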