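#' Electrode montage
#'
#' A montage is the set of electrode labels and their 3-D scalp positions.
#' Positions use an arbitrary but consistent length unit (only relative
#' Euclidean distances between electrodes matter to the algorithm). 2-D
#' coordinates are accepted and zero-padded in z.
#'
#' @param labels character vector of unique electrode names.
#' @param coords numeric matrix with one row per electrode and 2 or 3 columns.
#' @return An object of class `eeg_montage` with fields `labels` and `coords`
#'   (always M x 3).
#' @examples
#' m <- montage(c("A", "B", "C"), rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)))
#' montage_distances(m)
#' @export
montage <- function(labels, coords) {
  labels <- as.character(labels)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) == 2L) coords <- cbind(coords, 0)
  if (ncol(coords) != 3L)
    stop_invalid("montage coordinates must have 2 or 3 columns")
  if (length(labels) != nrow(coords))
    stop_invalid("number of labels (", length(labels),
                 ") does not match number of coordinate rows (", nrow(coords), ")")
  if (length(labels) < 2L)
    stop_invalid("a montage needs at least 2 electrodes")
  if (anyDuplicated(labels))
    stop_invalid("electrode labels must be unique")
  if (!all(is.finite(coords)))
    stop_invalid("montage coordinates must be finite")
  if (anyDuplicated(coords, MARGIN = 1))
    warning("montage contains electrodes with identical coordinates; ",
            "distance ties are broken by electrode index", call. = FALSE)
  dimnames(coords) <- list(labels, c("x", "y", "z"))
  structure(list(labels = labels, coords = coords), class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$labels), " electrodes (",
      paste(utils::head(x$labels, 4), collapse = ", "),
      if (length(x$labels) > 4) ", ..." else "", ")\n", sep = "")
  invisible(x)
}

#' Pairwise electrode distances
#'
#' Euclidean (chordal) distances between all electrode pairs.
#'
#' @param m an [montage()] object.
#' @return symmetric M x M numeric matrix with zero diagonal.
#' @export
montage_distances <- function(m) {
  stopifnot(inherits(m, "eeg_montage"))
  d <- as.matrix(stats::dist(m$coords))
  dimnames(d) <- list(m$labels, m$labels)
  d
}

#' Indices of the L nearest electrodes
#'
#' Returns the indices of the `L` electrodes closest to electrode `k`,
#' including `k` itself (self-distance zero). `k` is listed first, the rest in
#' ascending distance; distance ties are broken by ascending electrode index so
#' plans are deterministic.
#'
#' @param distances symmetric distance matrix from [montage_distances()].
#' @param k electrode index (1-based).
#' @param L neighborhood size, `1 <= L <= M`.
#' @return integer vector of length `L`, first element `k`.
#' @export
neighbor_indices <- function(distances, k, L) {
  M <- nrow(distances)
  if (L < 1L || L > M)
    stop_invalid("L must be between 1 and the number of electrodes (", M, ")")
  if (k < 1L || k > M) stop_invalid("electrode index k out of range")
  ord <- order(distances[, k], seq_len(M))
  ord <- c(k, ord[ord != k])  # self first even under zero-distance ties
  as.integer(ord[seq_len(L)])
}

#' Subspace selection matrix
#'
#' Builds the binary L x M matrix whose rows are the standard basis vectors of
#' the electrodes in `idx`: multiplying a channels-by-samples matrix extracts
#' exactly those channels, in that order.
#'
#' @param idx integer vector of distinct channel indices.
#' @param M total channel count.
#' @return L x M matrix with entries in \{0, 1\}, one 1 per row.
#' @export
projection_matrix <- function(idx, M) {
  idx <- as.integer(idx)
  if (anyDuplicated(idx)) stop_invalid("projection indices must be distinct")
  if (any(idx < 1L | idx > M)) stop_invalid("projection indices out of range 1..", M)
  P <- matrix(0, length(idx), M)
  P[cbind(seq_along(idx), idx)] <- 1
  P
}

#' Build the electrode-neighborhood subspace plan
#'
#' Constructs one subspace per electrode: the `L` channels nearest to it. The
#' selection matrices are stacked into the (M*L) x M matrix `P`; because each
#' row of each block holds a single 1, the columns of `P` are orthogonal with
#' squared norm `c_j` = number of neighborhoods containing electrode `j`, so
#' the Moore-Penrose pseudoinverse has the closed form `diag(1/c) t(P)` (this
#' is verified against an SVD pseudoinverse in the test suite).
#'
#' @param m an [montage()] object.
#' @param L subspace dimension; the recommended operating range is 10--20 with
#'   default 12 (a warning is issued outside that range unless `L == M` for
#'   small montages).
#' @return object of class `subspace_plan` with fields `L`, `M`,
#'   `neighbor_lists`, `projections`, `stacked`, `pinv`, `counts`.
#' @export
build_subspace_plan <- function(m, L = 12L) {
  stopifnot(inherits(m, "eeg_montage"))
  M <- length(m$labels)
  L <- as.integer(L)
  if (L < 2L || L > M)
    stop_invalid("L must satisfy 2 <= L <= M (= ", M, ")")
  if ((L < 10L || L > 20L) && L != M)
    warning("subspace dimension L = ", L,
            " is outside the recommended range 10-20", call. = FALSE)
  d <- montage_distances(m)
  nb <- lapply(seq_len(M), function(k) neighbor_indices(d, k, L))
  proj <- lapply(nb, projection_matrix, M = M)
  P <- do.call(rbind, proj)
  counts <- colSums(P)
  stopifnot(all(counts >= 1))           # guaranteed: k is in its own list
  pinv <- t(P) / counts                 # closed form for orthogonal columns
  structure(list(L = L, M = M, neighbor_lists = nb, projections = proj,
                 stacked = P, pinv = pinv, counts = counts,
                 labels = m$labels),
            class = "subspace_plan")
}

#' @export
print.subspace_plan <- function(x, ...) {
  cat("<subspace_plan> M =", x$M, "electrodes, L =", x$L,
      "channels per subspace,", length(x$neighbor_lists), "subspaces\n")
  invisible(x)
}

# Generic pseudoinverse via SVD; used when a caller supplies custom projection
# matrices whose columns are not orthogonal.
pseudo_inverse <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

#' Load a montage from a plain-text file
#'
#' One electrode per line: `label x y z` (whitespace separated, z optional,
#' `#` starts a comment). See [standard_montage()] for packaged layouts.
#'
#' @param path file path.
#' @return an [montage()] object.
#' @export
load_montage <- function(path) {
  if (!file.exists(path)) stop_invalid("montage file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) < 2L) stop_invalid("montage file has fewer than 2 electrodes: ", path)
  labels <- character(length(keep))
  coords <- matrix(NA_real_, length(keep), 3)
  for (i in seq_along(keep)) {
    ln <- keep[i]
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(f) < 3L || length(f) > 4L)
      stop_invalid("malformed montage line ", ln, " in ", path,
                   ": expected 'label x y [z]'")
    xyz <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(xyz))
      stop_invalid("non-numeric coordinate on montage line ", ln, " in ", path)
    labels[i] <- f[1]
    coords[i, ] <- c(xyz, 0)[1:3]
  }
  montage(labels, coords)
}

#' Write a montage to the plain-text format read by [load_montage()]
#' @param m an [montage()] object.
#' @param path destination file.
#' @export
write_montage <- function(m, path) {
  stopifnot(inherits(m, "eeg_montage"))
  lines <- sprintf("%s %.6f %.6f %.6f", m$labels,
                   m$coords[, 1], m$coords[, 2], m$coords[, 3])
  writeLines(c("# label x y z", lines), path)
  invisible(path)
}

# Evenly spread n points on the upper unit hemisphere (Fibonacci lattice).
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n)
  z <- (i - 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- 2 * pi * i * (1 - 1 / ((1 + sqrt(5)) / 2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Nominal 10-20 layout (21 positions) on the unit sphere: vertex at (0,0,1),
# +x towards the nasion. Midline and ring electrodes follow the standard
# 10/20 percentage arcs; intermediate positions are normalized arc midpoints.
montage_1020_coords <- function() {
  sph <- function(theta_deg, phi_deg) {
    t <- theta_deg * pi / 180; p <- phi_deg * pi / 180
    c(sin(t) * cos(p), sin(t) * sin(p), cos(t))
  }
  mid <- function(a, b) { v <- a + b; v / sqrt(sum(v^2)) }
  pos <- list(
    Fpz = sph(72, 0),   Fz = sph(36, 0),   Cz = sph(0, 0),
    Pz  = sph(36, 180), Oz = sph(72, 180),
    Fp1 = sph(72, 18),  Fp2 = sph(72, -18),
    F7  = sph(72, 54),  F8  = sph(72, -54),
    T7  = sph(72, 90),  T8  = sph(72, -90),
    P7  = sph(72, 126), P8  = sph(72, -126),
    O1  = sph(72, 162), O2  = sph(72, -162),
    C3  = sph(36, 90),  C4  = sph(36, -90)
  )
  pos$F3 <- mid(pos$Fz, pos$F7); pos$F4 <- mid(pos$Fz, pos$F8)
  pos$P3 <- mid(pos$Pz, pos$P7); pos$P4 <- mid(pos$Pz, pos$P8)
  order21 <- c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
               "T7", "C3", "Cz", "C4", "T8",
               "P7", "P3", "Pz", "P4", "P8", "O1", "Oz", "O2")
  do.call(rbind, pos[order21])
}

#' Packaged montage layouts
#'
#' Three nominal scalp layouts on the unit hemisphere: `"hd111"` (111-channel
#' high-density Fibonacci lattice), `"1010"` (61-channel 10-10-density
#' Fibonacci lattice) and `"1020"` (the 21 standard 10-20 positions). The same
#' layouts ship as plain-text files under `inst/extdata` readable with
#' [load_montage()]. These are synthetic geometric layouts, not digitized
#' electrode positions.
#'
#' @param name one of `"hd111"`, `"1010"`, `"1020"`.
#' @return an [montage()] object.
#' @export
standard_montage <- function(name = c("hd111", "1010", "1020")) {
  name <- match.arg(name)
  switch(name,
    hd111 = montage(sprintf("E%03d", 1:111), fibonacci_hemisphere(111)),
    `1010` = montage(sprintf("E%02d", 1:61), fibonacci_hemisphere(61)),
    `1020` = {
      co <- montage_1020_coords()
      montage(rownames(co), co)
    })
}
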