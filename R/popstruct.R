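# Pairwise evolutionary distances on aligned rows (pairwise deletion) and
# Automatic Barcode Gap Discovery group delimitation.

#' Distance-estimation parameters
#'
#' @param model substitution model: \code{"p"} (raw proportion),
#'   \code{"JC"} (Jukes-Cantor) or \code{"K80"} (Kimura two-parameter).
#' @param gamma_shape gamma shape parameter alpha for rate variation across
#'   sites; \code{Inf} means uniform rates (the plain model).
#' @param deletion \code{"pairwise"} (drop columns gapped or ambiguous in
#'   either row of each pair) or \code{"complete"} (drop columns gapped in
#'   any row, applied by [distanceMatrix()]).
#' @return a named parameter list.
#' @export
distanceParams <- function(model = c("JC", "p", "K80"), gamma_shape = 1,
                           deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  if (!(gamma_shape > 0)) .stop_domain("gamma_shape must be positive")
  list(model = model, gamma_shape = gamma_shape, deletion = deletion)
}

#' Pairwise distance between two gapped aligned rows
#'
#' Columns gapped or \code{N} in either row are removed (pairwise
#' deletion). Under gamma rate variation with shape \code{alpha}:
#' \deqn{d_{JC} = \frac{3\alpha}{4}\left[(1 - 4p/3)^{-1/\alpha} - 1\right]}
#' and for K80 with transition proportion P and transversion proportion Q
#' \deqn{d = \frac{\alpha}{2}\left[(1-2P-Q)^{-1/\alpha}-1\right] +
#'       \frac{\alpha}{4}\left[(1-2Q)^{-1/\alpha}-1\right].}
#' With \code{alpha = Inf} these reduce to the familiar logarithmic closed
#' forms. At \code{alpha = 1} the JC correction simplifies to
#' \eqn{p / (1 - 4p/3)}.
#'
#' @param a,b gapped rows of equal column count.
#' @param params a [distanceParams()] list.
#' @return the distance (non-negative scalar).
#' @export
pairwiseDistance <- function(a, b, params = distanceParams()) {
  x <- .chars(a); y <- .chars(b)
  if (length(x) != length(y))
    .stop_domain("rows differ in column count")
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  if (!any(ok))
    .stop_domain("no columns with residues in both rows")
  x <- x[ok]; y <- y[ok]
  nv <- length(x)
  diff <- x != y
  p <- sum(diff) / nv
  model <- params$model; alpha <- params$gamma_shape
  if (model == "p") return(p)
  if (model == "JC") {
    if (p >= 0.75)
      .stop_domain("p = %.3f >= 3/4: JC distance undefined (saturation)", p)
    if (is.infinite(alpha)) return(-0.75 * log1p(-4 * p / 3))
    # expm1 keeps precision for large alpha, where the exponent is tiny
    return(0.75 * alpha * expm1(-log1p(-4 * p / 3) / alpha))
  }
  # K80
  ts <- (x == "A" & y == "G") | (x == "G" & y == "A") |
        (x == "C" & y == "T") | (x == "T" & y == "C")
  P <- sum(ts) / nv
  Q <- p - P
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    .stop_domain("K80 distance undefined (saturation): P=%.3f Q=%.3f", P, Q)
  if (is.infinite(alpha)) return(-0.5 * log(w1) - 0.25 * log(w2))
  0.5 * alpha * expm1(-log(w1) / alpha) +
    0.25 * alpha * expm1(-log(w2) / alpha)
}

#' Distance matrix over the rows of an alignment
#'
#' @param x an \linkS4class{AnchoredMSA}, or a named character vector of
#'   gapped rows sharing one column space.
#' @param params a [distanceParams()] list.
#' @return symmetric numeric matrix with zero diagonal and row/col labels.
#' @export
distanceMatrix <- function(x, params = distanceParams()) {
  rows <- if (is(x, "AnchoredMSA")) alnRows(x) else x
  k <- length(rows)
  if (is.null(names(rows))) names(rows) <- paste0("seq", seq_len(k))
  if (params$deletion == "complete") {
    mats <- do.call(rbind, lapply(rows, .chars))
    keep <- apply(mats, 2L, function(cc) all(cc %in% c("A", "C", "G", "T")))
    rows <- apply(mats[, keep, drop = FALSE], 1L, paste, collapse = "")
  }
  D <- matrix(0, k, k, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    D[i, j] <- D[j, i] <- pairwiseDistance(rows[[i]], rows[[j]], params)
  }
  D
}

#' Write / read a PHYLIP-style square distance matrix
#' @param D labelled symmetric matrix.
#' @param path file path.
#' @return \code{path} (write) or the matrix (read).
#' @export
writeDistanceMatrix <- function(D, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d", nrow(D)), con)
  for (i in seq_len(nrow(D)))
    writeLines(paste(c(rownames(D)[i], sprintf("%.10f", D[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path) {
  lines <- readLines(path)
  k <- as.integer(lines[1])
  parts <- strsplit(lines[1 + seq_len(k)], "\t")
  labs <- vapply(parts, `[`, "", 1L)
  D <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(k)))
  dimnames(D) <- list(labs, labs)
  D
}

#' ABGD parameters
#'
#' @param prior prior maximal intraspecific distance P.
#' @param gap_width relative gap width X: a jump between consecutive sorted
#'   distances is significant when it exceeds \code{X * max(d_low, prior)},
#'   where \code{d_low} is the distance below the jump.
#' @param min_group groups smaller than this are not split further.
#' @return a named parameter list.
#' @export
abgdParams <- function(prior = 1e-3, gap_width = 1.5, min_group = 3L) {
  if (!(prior > 0) || !(gap_width > 0))
    .stop_domain("prior and gap_width must be positive")
  list(prior = prior, gap_width = gap_width,
       min_group = as.integer(min_group))
}

#' Automatic Barcode Gap Discovery partition
#'
#' Recursive delimitation of intraspecific groups from a pairwise distance
#' matrix: the sorted distances are scanned for the first significant gap
#' above the prior-limited intraspecific range (a jump exceeding
#' \code{gap_width} times \code{max(d_below, prior)}); samples are split
#' into the connected components of the graph whose edges are the pairs
#' below the gap, and the procedure recurses inside each component until no
#' significant gap remains or components fall below \code{min_group}.
#' Deterministic and invariant to label order; with no gap the result is a
#' single group.
#'
#' @param D labelled symmetric distance matrix.
#' @param params an [abgdParams()] list.
#' @return list with \code{groups} (named integer vector label -> group
#'   id), \code{n_groups}, and \code{gaps} (data.frame of the splits
#'   applied: threshold, gap size).
#' @export
abgdPartition <- function(D, params = abgdParams()) {
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("seq", seq_len(nrow(D)))
  if (nrow(D) < 2L)
    return(list(groups = setNames(rep(1L, nrow(D)), labs), n_groups = 1L,
                gaps = data.frame(threshold = numeric(), gap = numeric())))
  gaps_log <- list()
  split_rec <- function(idx) {
    if (length(idx) < params$min_group) return(list(idx))
    sub <- D[idx, idx, drop = FALSE]
    dv <- sort(sub[upper.tri(sub)])
    thr <- .abgd_find_gap(dv, params$prior, params$gap_width)
    if (!is.list(thr)) return(list(idx))
    gaps_log[[length(gaps_log) + 1L]] <<-
      data.frame(threshold = thr$threshold, gap = thr$gap)
    comp <- .components(sub <= thr$threshold)
    if (max(comp) == 1L) return(list(idx))
    out <- list()
    for (g in seq_len(max(comp)))
      out <- c(out, split_rec(idx[comp == g]))
    out
  }
  parts <- split_rec(seq_along(labs))
  groups <- integer(length(labs))
  for (g in seq_along(parts)) groups[parts[[g]]] <- g
  names(groups) <- labs
  gaps <- if (length(gaps_log)) do.call(rbind, gaps_log) else
    data.frame(threshold = numeric(), gap = numeric())
  list(groups = groups, n_groups = length(parts), gaps = gaps)
}

# first significant jump in the sorted distance vector
.abgd_find_gap <- function(dv, prior, X) {
  if (length(dv) < 2L) return(NA)
  jumps <- diff(dv)
  for (i in seq_along(jumps)) {
    ref <- max(dv[i], prior)
    if (jumps[i] > X * ref)
      return(list(threshold = dv[i] + jumps[i] / 2, gap = jumps[i]))
  }
  NA
}

# connected components of a logical adjacency matrix (diagonal TRUE)
.components <- function(adj) {
  k <- nrow(adj)
  comp <- integer(k); cur <- 0L
  for (s in seq_len(k)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v]) next
      comp[v] <- cur
      nb <- which(adj[v, ] & comp == 0L)
      queue <- c(queue, nb)
    }
  }
  comp
}
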