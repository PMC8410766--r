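#' Pick 1D peaks in every column and row of a 2D spectrum
#'
#' Applies the 1D picker to every column (sections indexed by column,
#' positions along rows) and every row (sections indexed by row,
#' positions along columns).  A single global noise estimate of the 2D
#' matrix sets the amplitude cutoff for all sections; sections whose
#' maximum is below the cutoff are skipped.  Each section is
#' max-normalized before the forward pass and decoded amplitudes are
#' restored to original units.  All sections of an orientation are run
#' through the network in one batched forward pass.
#'
#' @param spectrum An \linkS4class{NMRSpectrum2D} or numeric matrix.
#' @param net A trained \linkS4class{PickerNet}.
#' @param config A \code{\link{pickConfig}}.
#' @return List with \code{colPicks} (per-column peak tables, positions
#'   = row coordinates), \code{rowPicks} (per-row, positions = column
#'   coordinates) and \code{noise}.
#' @export
pickSections <- function(spectrum, net, config = pickConfig()) {
  m <- if (is(spectrum, "NMRSpectrum2D")) intensities(spectrum)
       else as.matrix(spectrum)
  rf <- receptiveField(net@arch)
  if (nrow(m) < rf || ncol(m) < rf)
    stop("both dimensions must be at least the receptive field (", rf, ")")
  noise <- estimateNoise(as.numeric(m), config$kNoise)
  pickAll <- function(mat) {
    # sections are the columns of mat
    nS <- ncol(mat)
    maxima <- apply(mat, 2, max)
    active <- which(maxima > noise$cutoff & maxima > 0)
    picks <- rep(list(.emptyPeaks1D()), nS)
    if (length(active)) {
      X <- sweep(mat[, active, drop = FALSE], 2, maxima[active], "/")
      out <- forwardNetwork(net, X)
      for (j in seq_along(active)) {
        fw <- list(classScores = out$classScores[, , j],
                   regressor = out$regressor[, , j])
        picks[[active[j]]] <- .pickVector(mat[, active[j]], net, config,
                                          noise$cutoff, noise$sigma,
                                          forward = fw)
      }
    }
    picks
  }
  list(colPicks = pickAll(m), rowPicks = pickAll(t(m)), noise = noise)
}

#' Chain 1D picks across adjacent sections into peak lines
#'
#' Greedy nearest-first linking: picks in section s extend lines whose
#' last node sits in section s-1 and whose position differs by at most
#' \code{linkTol} points; each pick joins at most one line and unmatched
#' picks open new lines.  Lines shorter than \code{minLineLength} nodes
#' are discarded.  Section indices within a line are strictly increasing
#' and gap-free.
#'
#' @param sectionPicks List of per-section peak tables (positions in the
#'   transverse coordinate).
#' @param orientation "column_line" or "row_line" (annotation only).
#' @param linkTol Adjacency tolerance in points.
#' @param minLineLength Minimum node count.
#' @return List of peak lines; each line is a data.frame with columns
#'   \code{section, position, class, confidence, amplitude, fwhh, eta}.
#' @export
buildLines <- function(sectionPicks, orientation = c("column_line", "row_line"),
                       linkTol = 2, minLineLength = 3) {
  orientation <- match.arg(orientation)
  stopifnot(linkTol > 0)
  open <- list()    # each: list(lastSection, rows = data.frame)
  closed <- list()
  for (s in seq_along(sectionPicks)) {
    pk <- sectionPicks[[s]]
    extendable <- which(vapply(open, function(l) l$lastSection == s - 2L, TRUE))
    used <- logical(nrow(pk))
    if (length(extendable) && nrow(pk)) {
      cand <- expand.grid(li = extendable, pi = seq_len(nrow(pk)))
      cand$d <- abs(vapply(seq_len(nrow(cand)), function(i) {
        tail(open[[cand$li[i]]]$rows$position, 1) - pk$position[cand$pi[i]]
      }, 0))
      cand <- cand[cand$d <= linkTol, , drop = FALSE]
      cand <- cand[order(cand$d), , drop = FALSE]
      takenLine <- logical(length(open))
      for (i in seq_len(nrow(cand))) {
        li <- cand$li[i]; pi <- cand$pi[i]
        if (takenLine[li] || used[pi]) next
        takenLine[li] <- TRUE
        used[pi] <- TRUE
        row <- data.frame(section = s - 1L, position = pk$position[pi],
                          class = pk$class[pi], confidence = pk$confidence[pi],
                          amplitude = pk$amplitude[pi], fwhh = pk$fwhh[pi],
                          eta = pk$eta[pi])
        open[[li]]$rows <- rbind(open[[li]]$rows, row)
        open[[li]]$lastSection <- s - 1L
      }
    }
    # close lines not extended at this section
    if (length(open)) {
      stale <- open[vapply(open, function(l) l$lastSection < s - 1L, TRUE)]
      closed <- c(closed, lapply(stale, `[[`, "rows"))
      open <- open[vapply(open, function(l) l$lastSection == s - 1L, TRUE)]
    }
    # unmatched picks open new lines
    for (pi in which(!used)) {
      open[[length(open) + 1L]] <- list(
        lastSection = s - 1L,
        rows = data.frame(section = s - 1L, position = pk$position[pi],
                          class = pk$class[pi], confidence = pk$confidence[pi],
                          amplitude = pk$amplitude[pi], fwhh = pk$fwhh[pi],
                          eta = pk$eta[pi]))
    }
  }
  closed <- c(closed, lapply(open, `[[`, "rows"))
  closed <- Filter(function(l) nrow(l) >= minLineLength, closed)
  lapply(closed, function(l) { attr(l, "orientation") <- orientation; l })
}

#' Intersect column lines with row lines into cross-peak candidates
#'
#' A column line passing through column c at row position r matches a row
#' line passing through row r' at column position c' when both |r - r'|
#' and |c - c'| are at most \code{matchTol}; the closest such node pair
#' defines one candidate per line pair.
#'
#' @param colLines,rowLines Output of \code{\link{buildLines}}.
#' @param matchTol Match tolerance in points.
#' @return data.frame of candidates (one per matched line pair) with the
#'   contributing node parameters.
#' @export
intersectLines <- function(colLines, rowLines, matchTol = 1.5) {
  out <- list()
  for (ci in seq_along(colLines)) {
    cl <- colLines[[ci]]
    for (ri in seq_along(rowLines)) {
      rl <- rowLines[[ri]]
      # col-line node: (column = section, row = position)
      # row-line node: (row = section, column = position)
      best <- NULL
      for (i in seq_len(nrow(cl))) {
        dr <- abs(cl$position[i] - rl$section)
        dc <- abs(cl$section[i] - rl$position)
        ok <- which(dr <= matchTol & dc <= matchTol)
        if (!length(ok)) next
        j <- ok[which.min(dr[ok] + dc[ok])]
        d <- dr[j] + dc[j]
        if (is.null(best) || d < best$d) best <- list(i = i, j = j, d = d)
      }
      if (is.null(best)) next
      i <- best$i; j <- best$j
      out[[length(out) + 1L]] <- data.frame(
        posRow = cl$position[i], posCol = rl$position[j],
        fwhhRow = cl$fwhh[i], fwhhCol = rl$fwhh[j],
        etaRow = cl$eta[i], etaCol = rl$eta[j],
        amplitude = (cl$amplitude[i] + rl$amplitude[j]) / 2,
        confidence = min(cl$confidence[i], rl$confidence[j]),
        classRow = cl$class[i], classCol = rl$class[j],
        colLine = ci, rowLine = ri,
        colSection = cl$section[i], rowSection = rl$section[j])
    }
  }
  if (!length(out)) return(.emptyPeaks2D())
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

.emptyPeaks2D <- function() {
  data.frame(posRow = numeric(), posCol = numeric(), fwhhRow = numeric(),
             fwhhCol = numeric(), etaRow = numeric(), etaCol = numeric(),
             amplitude = numeric(), confidence = numeric(),
             classRow = integer(), classCol = integer(),
             colLine = integer(), rowLine = integer(),
             colSection = integer(), rowSection = integer())
}

#' Remove false line intersections
#'
#' An intersection whose contributing 1D picks are shoulder peaks
#' (Class 1) along both the row and the column direction is the crossing
#' of two other peaks' lines, not a real cross-peak, and is dropped.
#'
#' @param candidates Candidate table from \code{\link{intersectLines}}.
#' @return List with \code{kept} and \code{removed} candidate tables.
#' @export
removeFalseIntersections <- function(candidates) {
  false <- candidates$classRow == 1L & candidates$classCol == 1L
  list(kept = candidates[!false, , drop = FALSE],
       removed = candidates[false, , drop = FALSE])
}

#' Maximum tilt angle of a peak line
#'
#' Slides a \code{window}-node segment along the line (consecutive node
#' pairs when the line is shorter) and measures each segment's angle
#' arctan(|delta position| / delta section) in degrees against the
#' line's nominal axis; returns the maximum and the arg-max segment's
#' endpoints.
#'
#' @param line A peak line (see \code{\link{buildLines}}).
#' @param window Segment length in nodes.
#' @return List with \code{angle} (degrees) and \code{segment} (2 x 2
#'   matrix of endpoint (section, position) pairs); angle 0 for
#'   single-node lines.
#' @export
maxTiltAngle <- function(line, window = 3) {
  n <- nrow(line)
  if (n < 2)
    return(list(angle = 0, segment = NULL))
  w <- min(window, n)
  bestA <- -1
  bestSeg <- NULL
  for (i in seq_len(n - w + 1)) {
    j <- i + w - 1
    dp <- line$position[j] - line$position[i]
    ds <- line$section[j] - line$section[i]
    a <- atan2(abs(dp), ds) * 180 / pi
    if (a > bestA) {
      bestA <- a
      bestSeg <- rbind(c(line$section[i], line$position[i]),
                       c(line$section[j], line$position[j]))
    }
  }
  list(angle = bestA, segment = bestSeg)
}

#' Split a tilted intersection into two cross-peaks
#'
#' When both the column line and the row line through a kept candidate
#' have a most-tilted segment steeper than \code{angleCutoff} (14
#' degrees), the single intersection peak is replaced by two peaks at
#' the midpoints of the two segments' corresponding end positions
#' (endpoints paired by proximity); otherwise the candidate is returned
#' unchanged.
#'
#' @param candidate One-row candidate.
#' @param colLine,rowLine The contributing lines.
#' @param angleCutoff Degrees.
#' @param tiltWindow Segment window (nodes).
#' @param allowSplit Set FALSE when the contributing lines intersect
#'   other lines as well: the tilt split addresses the regime where
#'   every row and column shows a single 1D peak, so a line already
#'   resolved into several intersections is never split.
#' @return Candidate table with one or two rows (split rows get
#'   \code{origin = "split"}).
#' @export
splitTilted <- function(candidate, colLine, rowLine, angleCutoff = 14,
                        tiltWindow = 3, allowSplit = TRUE) {
  # tilt is measured locally: only segments within about one FWHH of the
  # intersection can describe the overlapping pair the split resolves
  near <- function(line, center, fwhh) {
    keep <- abs(line$section - center) <= max(tiltWindow, ceiling(fwhh))
    sub <- line[keep, , drop = FALSE]
    # tilt is judged on the amplitude core of the line: in a genuinely
    # merged pair the transition happens at full height, whereas weak
    # tail sections only contribute sub-pixel position wobble
    sub[sub$amplitude >= 0.5 * max(sub$amplitude), , drop = FALSE]
  }
  if (!is.null(candidate$colSection)) {
    colLine <- near(colLine, candidate$colSection, candidate$fwhhCol)
    rowLine <- near(rowLine, candidate$rowSection, candidate$fwhhRow)
  }
  candidate$origin <- "picked"
  if (!allowSplit) return(candidate)
  # end-to-end drift of the core window: a merged pair drifts
  # monotonically from one component to the other, whereas sub-pixel
  # noise wobble (which can make individual short segments steep)
  # cancels over the window
  drift <- function(line) {
    n <- nrow(line)
    if (n < 2) return(list(angle = 0, segment = NULL))
    list(angle = atan2(abs(line$position[n] - line$position[1]),
                       line$section[n] - line$section[1]) * 180 / pi,
         segment = rbind(c(line$section[1], line$position[1]),
                         c(line$section[n], line$position[n])))
  }
  tc <- drift(colLine)
  tr <- drift(rowLine)
  if (tc$angle <= angleCutoff || tr$angle <= angleCutoff)
    return(candidate)
  # column-line endpoints as (row, col) = (position, section);
  # row-line endpoints as (row, col) = (section, position)
  ce <- cbind(tc$segment[, 2], tc$segment[, 1])
  re <- cbind(tr$segment[, 1], tr$segment[, 2])
  d11 <- sum((ce[1, ] - re[1, ])^2) + sum((ce[2, ] - re[2, ])^2)
  d12 <- sum((ce[1, ] - re[2, ])^2) + sum((ce[2, ] - re[1, ])^2)
  if (d12 < d11) re <- re[2:1, , drop = FALSE]
  mid <- (ce + re) / 2
  out <- candidate[c(1, 1), , drop = FALSE]
  out$posRow <- mid[, 1]
  out$posCol <- mid[, 2]
  out$origin <- "split"
  rownames(out) <- NULL
  out
}

#' Assemble a cross-peak from a matched column node and row node
#'
#' Per-dimension width, Lorentzian fraction and sub-pixel position come
#' from the 1D pick that varies along that dimension (the column-line
#' node for the row dimension and vice versa); the amplitude is the mean
#' of the two 1D amplitudes (original intensity units) and the
#' confidence the lower of the two.
#'
#' @param colNode,rowNode One-row 1D peak tables.
#' @return One-row 2D peak table.
#' @export
assembleCrossPeak <- function(colNode, rowNode) {
  data.frame(posRow = colNode$position, posCol = rowNode$position,
             fwhhRow = colNode$fwhh, fwhhCol = rowNode$fwhh,
             etaRow = colNode$eta, etaCol = rowNode$eta,
             amplitude = (colNode$amplitude + rowNode$amplitude) / 2,
             confidence = min(colNode$confidence, rowNode$confidence),
             classRow = as.integer(colNode$class),
             classCol = as.integer(rowNode$class))
}

#' Pick cross-peaks in a 2D spectrum
#'
#' Full 2D pipeline: 1D picking of all rows and columns, chaining into
#' peak lines, line intersection, removal of Class-1-in-both false
#' intersections, tilted-intersection splitting, and assembly.  Peaks
#' are sorted by (row, column).
#'
#' @param spectrum An \linkS4class{NMRSpectrum2D} or numeric matrix.
#' @param net A trained \linkS4class{PickerNet}.
#' @param config A \code{\link{pickConfig}}; \code{config$maskCols}
#'   zeroes the given 0-based columns (e.g. a water band) before
#'   picking.
#' @return A \linkS4class{PeakSet} (kind "2d") whose metadata records the
#'   candidate, removed-intersection and line diagnostics.
#' @export
pickPeaks2D <- function(spectrum, net, config = pickConfig()) {
  m <- if (is(spectrum, "NMRSpectrum2D")) intensities(spectrum)
       else as.matrix(spectrum)
  if (!is.null(config$maskCols)) m[, config$maskCols + 1L] <- 0
  sec <- pickSections(m, net, config)
  colLines <- buildLines(sec$colPicks, "column_line", config$linkTol,
                         config$minLineLength)
  rowLines <- buildLines(sec$rowPicks, "row_line", config$linkTol,
                         config$minLineLength)
  cand <- intersectLines(colLines, rowLines, config$matchTol)
  flt <- removeFalseIntersections(cand)
  rows <- list()
  for (i in seq_len(nrow(flt$kept))) {
    ci <- flt$kept[i, , drop = FALSE]
    lonely <- sum(cand$colLine == ci$colLine) == 1 &&
      sum(cand$rowLine == ci$rowLine) == 1
    rows[[i]] <- splitTilted(ci, colLines[[ci$colLine]], rowLines[[ci$rowLine]],
                             config$angleCutoff, config$tiltWindow,
                             allowSplit = lonely)
  }
  pk <- if (length(rows)) do.call(rbind, rows) else
    cbind(.emptyPeaks2D(), data.frame(origin = character()))
  # near-coincident outputs (parallel duplicate lines) collapse to the
  # most confident one
  if (nrow(pk) > 1) {
    keep <- logical(nrow(pk))
    for (i in order(-pk$confidence)) {
      dup <- keep & abs(pk$posRow - pk$posRow[i]) <= config$matchTol &
        abs(pk$posCol - pk$posCol[i]) <= config$matchTol
      if (!any(dup)) keep[i] <- TRUE
    }
    pk <- pk[keep, , drop = FALSE]
  }
  pk <- pk[order(pk$posRow, pk$posCol),
           setdiff(names(pk), c("colLine", "rowLine", "colSection",
                                "rowSection")), drop = FALSE]
  rownames(pk) <- NULL
  new("PeakSet", peaks = pk, kind = "2d",
      metadata = list(noise = sec$noise, config = config,
                      candidates = cand, removed = flt$removed,
                      nColLines = length(colLines),
                      nRowLines = length(rowLines)))
}
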