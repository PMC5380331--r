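# Internal helpers: seeded evaluation, image bookkeeping, plain-text image IO,
# connected components, and a small config hash for provenance.

# Evaluate `expr` under a local RNG state seeded with `seed`; NULL seed leaves
# the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # initialise the stream so we can restore it
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# 4-connected component labelling of a logical matrix. Iterative minimum-label
# propagation; fine for the image sizes this package handles.
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  mode(mask) <- "logical"
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  if (!any(mask)) return(lab)
  nr <- nrow(mask)
  nc <- ncol(mask)
  repeat {
    new <- lab
    # propagate the minimum positive label from the 4-neighbourhood
    up    <- rbind(lab[-1, , drop = FALSE], rep(0L, nc))
    down  <- rbind(rep(0L, nc), lab[-nr, , drop = FALSE])
    left  <- cbind(rep(0L, nr), lab[, -nc, drop = FALSE])
    right <- cbind(lab[, -1, drop = FALSE], rep(0L, nr))
    for (nb in list(up, down, left, right)) {
      take <- mask & nb > 0L & (new == 0L | nb < new)
      new[take] <- nb[take]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  # compact labels to 1..k
  u <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

largest_component <- function(mask) {
  lab <- label_components(mask)
  if (!any(lab > 0L)) return(mask & FALSE)
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}

# Fill holes: background components not touching the image border belong to
# the foreground.
fill_holes <- function(mask) {
  lab <- label_components(!mask)
  if (!any(lab > 0L)) return(mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  mask | (lab > 0L & !(lab %in% border))
}

# ---- plain-text image IO (PGM P2); stacks are concatenated pages ----------

#' Write an image stack as plain-text PGM pages
#'
#' Images are stored as ASCII (P2) portable graymaps, one page per frame,
#' concatenated in a single file. Intensities are scaled to 16-bit integers;
#' the scale factor is recorded in a `# scale=` comment so [read_pgm_stack()]
#' restores the original values.
#'
#' @param x numeric matrix or 3-D array (rows x cols x frames).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pgm_stack <- function(x, path) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3L, all(is.finite(x)))
  maxval <- 65535L
  hi <- max(x)
  scale <- if (hi > 0) maxval / hi else 1
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(dim(x)[3])) {
    page <- round(x[, , k] * scale)
    writeLines(c("P2", sprintf("# scale=%.10g", scale),
                 sprintf("%d %d", ncol(page), nrow(page)),
                 as.character(maxval)), con)
    utils::write.table(page, con, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a plain-text PGM stack written by [write_pgm_stack()]
#'
#' @param path file path.
#' @return numeric 3-D array (rows x cols x frames).
#' @export
read_pgm_stack <- function(path) {
  lines <- readLines(path)
  pages <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!identical(lines[i], "P2")) stop_param("not a P2 PGM page at line %d", i)
    scale <- 1
    i <- i + 1L
    while (startsWith(lines[i], "#")) {
      m <- regmatches(lines[i], regexec("scale=([0-9.eE+-]+)", lines[i]))[[1]]
      if (length(m) == 2L) scale <- as.numeric(m[2])
      i <- i + 1L
    }
    dims <- as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]])
    nc <- dims[1]; nr <- dims[2]
    i <- i + 2L # skip maxval
    vals <- scan(text = lines[i:(i + nr - 1L)], quiet = TRUE)
    pages[[length(pages) + 1L]] <- matrix(vals, nr, nc, byrow = TRUE) / scale
    i <- i + nr
  }
  array(unlist(pages), c(dim(pages[[1]]), length(pages)))
}

# FNV-1a hash of a character string, returned as hex. Used for config
# provenance only (not cryptographic). 32-bit arithmetic done in doubles,
# multiplication split into 16-bit halves to stay within double precision.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    h_lo <- h %% 65536
    h_hi <- h %/% 65536
    h <- (h_lo * m + ((h_hi * m) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

# Smoothstep ramp on [0, 1].
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# Shoelace area and area centroid of a closed polygon given as n x 2 matrix
# (last vertex need not repeat the first).
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

polygon_centroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(p))
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}
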