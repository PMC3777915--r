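#' Build a hexagonal receptor lattice
#'
#' Constructs the triangular-tiled lattice of receptor dimers used by the
#' stochastic simulator.  Each dimer has up to six nearest neighbors (all
#' interior dimers have exactly six; boundary dimers fewer, i.e. the
#' boundary is open, not periodic).  Dimers are grouped into MWC signaling
#' complexes of exactly six dimers (two trimers of dimers), and the basic
#' hexagonal unit of the lattice holds three complexes, so a `w x h`-unit
#' lattice holds `18 * w * h` dimers and `3 * w * h` complexes.
#'
#' The dimers are placed on a rhombic patch of the triangular lattice in
#' axial coordinates, with rows `0 .. 3h - 1` and columns `0 .. 6w - 1`, and
#' indexed row-major (dimer id `= row * 6w + col + 1`; ids are 1-based at
#' the R level).  Each complex is a run of six consecutive dimers within a
#' row.  The simulator consumes only the adjacency, complex-membership and
#' assistance-neighborhood maps, which is all the hexagonal packing of the
#' receptor lattice constrains; the particular planar embedding is a
#' documented convention so that event traces are reproducible.
#'
#' @param width_units,height_units lattice extent in basic hexagonal units
#'   (three complexes, 18 dimers, per unit); positive integers.
#' @return An object of class `receptor_lattice` with fields
#'   `n_dimers`, `n_complexes`, `units`, `neighbors` (list of integer
#'   vectors), `complex_of` (integer vector), `complexes` (`n_complexes x 6`
#'   integer matrix).
#' @examples
#' lat <- build_lattice(2, 2)   # 72 dimers, 12 complexes
#' lat20 <- build_lattice(20, 20) # 7200 dimers, production scale
#' @export
build_lattice <- function(width_units, height_units = width_units) {
  w <- as.integer(width_units); h <- as.integer(height_units)
  if (length(w) != 1L || length(h) != 1L || is.na(w) || is.na(h) ||
      w < 1L || h < 1L)
    stop("lattice dimensions must be positive integers (hexagonal units)",
         call. = FALSE)
  nrow_ <- 3L * h; ncol_ <- 6L * w
  n <- nrow_ * ncol_
  idx <- function(r, c) r * ncol_ + c + 1L  # 1-based id
  # axial triangular adjacency: (r,c) ~ (r,c+-1), (r-1,c), (r-1,c+1),
  # (r+1,c-1), (r+1,c); interior sites have all six.
  nb <- vector("list", n)
  for (r in 0:(nrow_ - 1L)) {
    for (c in 0:(ncol_ - 1L)) {
      cand <- rbind(c(r, c - 1L), c(r, c + 1L),
                    c(r - 1L, c), c(r - 1L, c + 1L),
                    c(r + 1L, c - 1L), c(r + 1L, c))
      keep <- cand[, 1L] >= 0L & cand[, 1L] < nrow_ &
              cand[, 2L] >= 0L & cand[, 2L] < ncol_
      nb[[idx(r, c)]] <- sort(idx(cand[keep, 1L], cand[keep, 2L]))
    }
  }
  complex_of <- integer(n)
  for (r in 0:(nrow_ - 1L)) for (c in 0:(ncol_ - 1L))
    complex_of[idx(r, c)] <- r * w + c %/% 6L + 1L
  ncx <- 3L * w * h
  complexes <- matrix(0L, nrow = ncx, ncol = 6L)
  for (cx in seq_len(ncx)) complexes[cx, ] <- which(complex_of == cx)
  structure(list(n_dimers = n, n_complexes = ncx, units = c(w, h),
                 nrow = nrow_, ncol = ncol_,
                 neighbors = nb, complex_of = complex_of,
                 complexes = complexes),
            class = "receptor_lattice")
}

#' @export
print.receptor_lattice <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat(sprintf("Receptor lattice: %d dimers, %d MWC complexes (%d x %d units)\n",
              x$n_dimers, x$n_complexes, x$units[1], x$units[2]))
  cat(sprintf("  interior dimers (6 neighbors): %d; boundary dimers: %d\n",
              sum(deg == 6L), sum(deg < 6L)))
  invisible(x)
}

#' Assistance neighborhood of a dimer
#'
#' The set of dimers whose modification sites an enzyme tethered to `dimer`
#' can reach: the dimer itself plus its nearest neighbors.  Interior dimers
#' have a neighborhood of exactly seven dimers; boundary dimers fewer.
#' Neighborhoods of adjacent dimers overlap, so individual dimers belong to
#' several assistance neighborhoods.
#'
#' @param geometry a `receptor_lattice`.
#' @param dimer dimer id (1-based).
#' @return Sorted integer vector of dimer ids, including `dimer` itself.
#' @export
assistance_neighborhood <- function(geometry, dimer) {
  stopifnot(inherits(geometry, "receptor_lattice"))
  dimer <- as.integer(dimer)
  if (length(dimer) != 1L || is.na(dimer) || dimer < 1L ||
      dimer > geometry$n_dimers)
    stop("unknown dimer id", call. = FALSE)
  sort(c(dimer, geometry$neighbors[[dimer]]))
}

#' Validate lattice invariants
#'
#' Checks every structural invariant of a receptor lattice: symmetric and
#' irreflexive adjacency with at most six neighbors, complexes partitioning
#' the dimer set into groups of exactly six, and the counting identity
#' `n_dimers = 6 * n_complexes = 18 * units`.  Violations are reported, never
#' silently passed.
#'
#' @param geometry a `receptor_lattice` (possibly tampered with).
#' @return An object of class `lattice_report`: list with `ok` (logical),
#'   `violations` (character vector), `n_interior`, `n_boundary`.
#' @export
validate_geometry <- function(geometry) {
  v <- character(0)
  g <- geometry
  if (!is.list(g$neighbors) || length(g$neighbors) != g$n_dimers)
    v <- c(v, "neighbor map length does not match dimer count")
  deg <- lengths(g$neighbors)
  if (any(deg > 6L)) v <- c(v, "some dimers have more than six neighbors")
  for (d in seq_len(g$n_dimers)) {
    nbd <- g$neighbors[[d]]
    if (any(nbd == d)) { v <- c(v, "adjacency is not irreflexive"); break }
  }
  sym_bad <- FALSE
  for (d in seq_len(g$n_dimers)) {
    for (e in g$neighbors[[d]]) {
      if (!(d %in% g$neighbors[[e]])) { sym_bad <- TRUE; break }
    }
    if (sym_bad) break
  }
  if (sym_bad) v <- c(v, "adjacency is not symmetric")
  if (ncol(g$complexes) != 6L)
    v <- c(v, "complexes do not consist of exactly six dimers")
  memb <- sort(as.integer(g$complexes))
  if (!identical(memb, seq_len(g$n_dimers)))
    v <- c(v, "complexes do not partition the dimer set")
  cx_ok <- all(vapply(seq_len(g$n_complexes), function(cx)
    all(g$complex_of[g$complexes[cx, ]] == cx), logical(1)))
  if (!cx_ok)
    v <- c(v, "complex membership map disagrees with the complex table")
  if (g$n_dimers != 6L * g$n_complexes ||
      g$n_dimers != 18L * prod(g$units))
    v <- c(v, "dimer count != 6 x complexes = 18 x units")
  structure(list(ok = length(v) == 0L, violations = v,
                 n_interior = sum(deg == 6L), n_boundary = sum(deg < 6L)),
            class = "lattice_report")
}

#' @export
print.lattice_report <- function(x, ...) {
  if (x$ok) {
    cat(sprintf("lattice OK: %d interior, %d boundary dimers\n",
                x$n_interior, x$n_boundary))
  } else {
    cat("lattice INVALID:\n")
    for (msg in x$violations) cat("  - ", msg, "\n", sep = "")
  }
  invisible(x)
}

#' Export / import a lattice as plain text
#'
#' Writes the geometry as two tab-separated tables: an undirected edge list
#' (`dimer_a < dimer_b`) and a dimer-to-complex membership table, separated
#' by a `#` comment header.  [read_lattice()] reconstructs the geometry and
#' validates it.
#'
#' @param geometry a `receptor_lattice`.
#' @param path file path.
#' @return `write_lattice` returns `path` invisibly; `read_lattice` returns
#'   a `receptor_lattice`.
#' @export
write_lattice <- function(geometry, path) {
  stopifnot(inherits(geometry, "receptor_lattice"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# receptor_lattice units %d %d dimers %d",
                     geometry$units[1], geometry$units[2], geometry$n_dimers),
             con)
  writeLines("# edges", con)
  for (d in seq_len(geometry$n_dimers)) {
    up <- geometry$neighbors[[d]][geometry$neighbors[[d]] > d]
    if (length(up))
      writeLines(paste(d, up, sep = "\t"), con)
  }
  writeLines("# membership", con)
  writeLines(paste(seq_len(geometry$n_dimers), geometry$complex_of, sep = "\t"),
             con)
  invisible(path)
}

#' @rdname write_lattice
#' @export
read_lattice <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " ")[[1]]
  units <- as.integer(hdr[c(4, 5)])
  i_edges <- which(lines == "# edges")
  i_memb <- which(lines == "# membership")
  parse2 <- function(ls) {
    if (!length(ls)) return(matrix(integer(0), ncol = 2))
    do.call(rbind, lapply(strsplit(ls, "\t"), as.integer))
  }
  edges <- parse2(lines[(i_edges + 1):(i_memb - 1)])
  memb <- parse2(lines[(i_memb + 1):length(lines)])
  n <- nrow(memb)
  nb <- rep(list(integer(0)), n)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
  }
  nb <- lapply(nb, sort)
  complex_of <- integer(n); complex_of[memb[, 1]] <- memb[, 2]
  ncx <- max(complex_of)
  complexes <- matrix(0L, ncx, 6L)
  for (cx in seq_len(ncx)) complexes[cx, ] <- which(complex_of == cx)
  g <- structure(list(n_dimers = n, n_complexes = ncx, units = units,
                      nrow = NA_integer_, ncol = NA_integer_,
                      neighbors = nb, complex_of = complex_of,
                      complexes = complexes),
                 class = "receptor_lattice")
  rep <- validate_geometry(g)
  if (!rep$ok)
    stop("imported lattice violates invariants: ",
         paste(rep$violations, collapse = "; "), call. = FALSE)
  g
}

#' Per-complex and mean lattice activity from a methylation state
#'
#' Computes the instantaneous MWC activity of every complex from a per-dimer
#' methylation vector and the current ligand level, plus their average.
#' This is the same quantity the simulator tracks incrementally; the
#' from-scratch computation here is used for reporting and cross-checking.
#'
#' @param methyl integer vector of per-dimer methylation levels (0-8).
#' @param geometry a `receptor_lattice`.
#' @param params [mwc_params()].
#' @param L ligand concentration (uM).
#' @return List with `per_complex` (numeric vector) and `mean` (scalar).
#' @export
lattice_activity <- function(methyl, geometry, params = mwc_params(), L = 0) {
  stopifnot(inherits(geometry, "receptor_lattice"),
            length(methyl) == geometry$n_dimers)
  if (any(methyl < 0 | methyl > 8)) stop("methylation outside 0..8", call. = FALSE)
  m_cx <- as.numeric(rowSums(matrix(methyl[geometry$complexes],
                                    nrow = geometry$n_complexes)))
  a <- mwc_activity(m_cx, L, params)
  list(per_complex = a, mean = mean(a))
}
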