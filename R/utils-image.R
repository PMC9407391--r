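# Raster utilities shared by the rendering, segmentation, and skeleton stages.
# Images are plain numeric matrices indexed [row, col] = [y, x]; binary masks
# are logical matrices of the same shape. All neighborhood operations are
# vectorized (matrix shifts or FFT convolution) so no compiled code is needed.

#' Shift a matrix by whole pixels
#'
#' @param m numeric or logical matrix.
#' @param dr,dc row/column shift (positive moves content down/right).
#' @param fill value for vacated cells.
#' @return matrix of the same shape.
#' @keywords internal
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  rok <- rs >= 1 & rs <= nr
  cok <- cs >= 1 & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

#' 2-D convolution via FFT (circular; callers keep a border margin)
#'
#' The kernel is embedded centered on the origin so the output is aligned with
#' the input. Wrap-around affects only a kernel-radius border.
#'
#' @param m numeric matrix.
#' @param k odd-sized kernel matrix, smaller than `m` in both dimensions.
#' @keywords internal
conv_fft <- function(m, k, fm = NULL) {
  nr <- nrow(m); nc <- ncol(m)
  kr <- nrow(k); kc <- ncol(k)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1, kr <= nr, kc <= nc)
  K <- matrix(0, nr, nc)
  ri <- ((seq_len(kr) - (kr + 1) / 2) %% nr) + 1
  ci <- ((seq_len(kc) - (kc + 1) / 2) %% nc) + 1
  K[ri, ci] <- k
  if (is.null(fm)) fm <- stats::fft(m)
  Re(stats::fft(fm * stats::fft(K), inverse = TRUE)) / (nr * nc)
}

#' Sampled Gaussian and Gaussian-derivative 1-D kernels
#' @param sigma standard deviation in pixels.
#' @param order 0 (smooth), 1, or 2 (derivatives).
#' @keywords internal
gauss_kernel_1d <- function(sigma, order = 0) {
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  # derivative kernels are recentred to exact zero sum so constant images
  # are annihilated exactly (offset invariance of the ridge filter)
  switch(as.character(order),
    "0" = g,
    "1" = { k <- -x / sigma^2 * g; k - mean(k) },
    "2" = { k <- (x^2 - sigma^2) / sigma^4 * g; k - mean(k) },
    stop("order must be 0, 1 or 2")
  )
}

#' Gaussian blur
#' @param m numeric matrix.
#' @param sigma blur scale in pixels; 0 returns the input.
#' @return blurred matrix.
#' @export
gauss_blur <- function(m, sigma, fm = NULL) {
  if (sigma <= 0) return(m)
  k <- outer(gauss_kernel_1d(sigma, 0), gauss_kernel_1d(sigma, 0))
  conv_fft(m, k, fm = fm)
}

# Second-derivative (Hessian) responses at scale sigma, scale-normalized.
hessian_responses <- function(m, sigma, fm = NULL) {
  g0 <- gauss_kernel_1d(sigma, 0)
  g2 <- gauss_kernel_1d(sigma, 2)
  g1 <- gauss_kernel_1d(sigma, 1)
  s2 <- sigma^2
  if (is.null(fm)) fm <- stats::fft(m)
  list(
    xx = s2 * conv_fft(m, outer(g0, g2), fm = fm),   # d2/dx2, x = columns
    yy = s2 * conv_fft(m, outer(g2, g0), fm = fm),
    xy = s2 * conv_fft(m, outer(g1, g1), fm = fm)
  )
}

#' Multiscale bright-ridge response
#'
#' Largest negative Hessian eigenvalue (sign-flipped, clipped at zero) of the
#' Gaussian-smoothed image, maximized over scales. Bright curvilinear
#' structures on a dark background respond strongly; flat regions and edges
#' respond weakly.
#'
#' @param m numeric image matrix.
#' @param sigmas vector of scales in pixels.
#' @return non-negative response matrix.
#' @export
ridge_response <- function(m, sigmas = c(1, 1.5, 2.5), fm = NULL) {
  out <- matrix(0, nrow(m), ncol(m))
  if (is.null(fm)) fm <- stats::fft(m)
  for (s in sigmas) {
    h <- hessian_responses(m, s, fm = fm)
    tr <- h$xx + h$yy
    disc <- sqrt(pmax((h$xx - h$yy)^2 + 4 * h$xy^2, 0))
    lam_min <- (tr - disc) / 2
    out <- pmax(out, pmax(-lam_min, 0))
  }
  out
}

# ---- binary morphology ------------------------------------------------------

disk_kernel <- function(r) {
  ir <- ceiling(r)
  x <- seq(-ir, ir)
  k <- outer(x, x, function(a, b) as.numeric(a^2 + b^2 <= r^2 + 1e-9))
  k
}

#' Binary dilation / erosion with a Euclidean disk
#' @param mask logical matrix.
#' @param r disk radius in pixels; 0 returns the input.
#' @return logical matrix.
#' @export
dilate_disk <- function(mask, r) {
  if (r <= 0) return(mask)
  k <- disk_kernel(r)
  conv_fft(mask * 1, k) > 0.5
}

#' @rdname dilate_disk
#' @export
erode_disk <- function(mask, r) {
  if (r <= 0) return(mask)
  !dilate_disk(!mask, r)
}

#' Morphological closing (dilate then erode) with a disk
#' @inheritParams dilate_disk
#' @export
close_disk <- function(mask, r) {
  if (r <= 0) return(mask)
  erode_disk(dilate_disk(mask, r), r)
}

#' Morphological closing with a (2r+1) square (Chebyshev) element
#'
#' A square element bridges an axis-aligned gap of up to 2r px between thin
#' structures, which a Euclidean disk of the same radius does not.
#'
#' @inheritParams dilate_disk
#' @export
close_box <- function(mask, r) {
  if (r <= 0) return(mask)
  k <- matrix(1, 2 * r + 1, 2 * r + 1)
  dil <- conv_fft(mask * 1, k) > 0.5
  !(conv_fft((!dil) * 1, k) > 0.5)
}

# One-step 8-connected erosion by matrix shifts (border pixels erode).
erode8_step <- function(mask) {
  m <- mask * 1
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out * shift_mat(m, dr, dc, fill = 0)
  }
  out > 0
}

#' Integer depth map by iterated 8-connected erosion
#'
#' `depth[p]` counts how many erosions pixel `p` survives; the maximum sits at
#' the center of the thickest structure (used to locate the soma).
#'
#' @param mask logical matrix.
#' @param max_iter erosion cap.
#' @return integer matrix.
#' @export
erosion_depth <- function(mask, max_iter = 25L) {
  depth <- matrix(0L, nrow(mask), ncol(mask))
  cur <- mask
  it <- 0L
  while (any(cur) && it < max_iter) {
    depth <- depth + cur
    cur <- erode8_step(cur)
    it <- it + 1L
  }
  depth
}

#' Label 8-connected components of a binary mask
#'
#' @param mask logical matrix.
#' @return integer matrix; 0 = background, components numbered from 1 in
#'   decreasing size order.
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0) return(lab)
  pos <- integer(nr * nc)
  pos[idx] <- seq_along(idx)
  edges <- NULL
  # forward neighbors: S, E, SE, NE (linear index offsets)
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  ee <- vector("list", length(offs))
  for (i in seq_along(offs)) {
    dr <- offs[[i]][1]; dc <- offs[[i]][2]
    r2 <- r + dr; c2 <- cc + dc
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- idx[ok] + dr + dc * nr
    ok2 <- mask[j]
    ee[[i]] <- cbind(pos[idx[ok][ok2]], pos[j[ok2]])
  }
  edges <- do.call(rbind, ee)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  # renumber by decreasing size
  ord <- order(comp$csize, decreasing = TRUE)
  remap <- integer(length(ord)); remap[ord] <- seq_along(ord)
  lab[idx] <- remap[comp$membership]
  lab
}

# ---- skeletonization (Zhang-Suen thinning) ----------------------------------

#' Topology-preserving thinning to a 1-pixel skeleton
#'
#' Classic two-subiteration Zhang-Suen thinning, fully vectorized over the
#' image. Connectivity (8-connected foreground) and endpoints are preserved.
#'
#' @param mask logical matrix.
#' @return logical matrix of centerline pixels.
#' @export
thin_mask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  # pad with a background ring so neighbor indexing never wraps
  nrp <- nr + 2L
  m <- matrix(FALSE, nrp, nc + 2L)
  m[2:(nr + 1), 2:(nc + 1)] <- mask
  # neighbor order P2..P9 = N, NE, E, SE, S, SW, W, NW (column-major offsets)
  offs <- c(-1L, -1L + nrp, nrp, 1L + nrp, 1L, 1L - nrp, -nrp, -1L - nrp)
  act <- which(m)   # indices of foreground pixels still alive
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      if (length(act) == 0) break
      p <- matrix(FALSE, length(act), 8L)
      for (k in 1:8) p[, k] <- m[act + offs[k]]
      B <- rowSums(p)
      A <- integer(length(act))
      for (k in 1:8) {
        k2 <- if (k == 8L) 1L else k + 1L
        A <- A + (!p[, k] & p[, k2])
      }
      if (step == 1) {
        c1 <- !(p[, 1] & p[, 3] & p[, 5])   # P2*P4*P6 == 0
        c2 <- !(p[, 3] & p[, 5] & p[, 7])   # P4*P6*P8 == 0
      } else {
        c1 <- !(p[, 1] & p[, 3] & p[, 7])   # P2*P4*P8 == 0
        c2 <- !(p[, 1] & p[, 5] & p[, 7])   # P2*P6*P8 == 0
      }
      del <- B >= 2 & B <= 6 & A == 1L & c1 & c2
      if (any(del)) {
        m[act[del]] <- FALSE
        act <- act[!del]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  idx <- which(m)
  rp <- ((idx - 1L) %% nrp) + 1L
  cp <- ((idx - 1L) %/% nrp) + 1L
  out <- matrix(FALSE, nr, nc)
  out[cbind(rp - 1L, cp - 1L)] <- TRUE
  out
}

# ---- PGM image I/O ----------------------------------------------------------

#' Read / write portable graymap (PGM) images
#'
#' P2 (ASCII) and P5 (binary) graymaps with 8- or 16-bit depth. Images are
#' stored with gray values scaled to `[0, maxval]`; `read_pgm` returns values
#' rescaled to `[0, 1]`.
#'
#' @param path file path.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {
    # read one whitespace-delimited token, skipping comments
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0) stop("unexpected EOF in PGM header")
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0 || ch == "\n") break
        }
      } else if (!grepl("[[:space:]]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0 || grepl("[[:space:]]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- tok()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  nc <- as.integer(tok()); nr <- as.integer(tok()); maxval <- as.integer(tok())
  n <- nr * nc
  if (magic == "P5") {
    bytes <- if (maxval > 255) 2L else 1L
    raw <- readBin(con, "integer", n = n, size = bytes, signed = FALSE,
                   endian = "big")
    v <- raw
  } else {
    v <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  m <- matrix(v, nrow = nr, ncol = nc, byrow = TRUE)
  m / maxval
}

#' @rdname read_pgm
#' @param m numeric matrix in `[0, 1]` (values are clipped).
#' @param maxval 255 or 65535.
#' @param ascii write ASCII P2 (text) instead of binary P5.
#' @export
write_pgm <- function(m, path, maxval = 65535L, ascii = FALSE) {
  v <- round(pmin(pmax(m, 0), 1) * maxval)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxval)), con)
    writeLines(apply(v, 1, paste, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0("P5\n", ncol(m), " ", nrow(m), "\n", maxval, "\n"), con,
              eos = NULL)
    writeBin(as.integer(t(v)), con, size = if (maxval > 255) 2L else 1L,
             endian = "big")
  }
  invisible(path)
}

# Run code with a private RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
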