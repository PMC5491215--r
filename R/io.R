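# Standard-format readers and writers: SWC morphologies, event CSVs, summary
# curves, and the descriptive-statistics record.

#' Read a neuron morphology from an SWC file
#'
#' Parses the standard 7-column SWC format (`id type x y z radius parent`,
#' `#` comments, parent `-1` marking the root) and builds the corresponding
#' rooted network: each parent-child link becomes one straight segment.
#' Consecutive nodes with identical coordinates would create zero-length
#' segments; they are collapsed into one vertex with a warning.
#'
#' @param path file path.
#' @return a `linnet3d` rooted at the SWC root node.
#' @export
read_swc <- function(path) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineno <- which(keep)
  if (!any(keep)) stopf("%s: no data lines", path)
  fields <- strsplit(trimws(raw[keep]), "\\s+")
  nfield <- lengths(fields)
  if (any(nfield != 7L)) {
    stopf("%s: line %d has %d fields, expected 7", path,
          lineno[which(nfield != 7L)[1L]], nfield[nfield != 7L][1L])
  }
  tab <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 7L, byrow = TRUE)
  if (anyNA(tab)) {
    stopf("%s: non-numeric field on line %d", path, lineno[which(rowSums(is.na(tab)) > 0)[1L]])
  }
  ids <- as.integer(tab[, 1L])
  parent <- as.integer(tab[, 7L])
  if (anyDuplicated(ids)) {
    stopf("%s: duplicate node id on line %d", path, lineno[which(duplicated(ids))[1L]])
  }
  rooti <- which(parent == -1L)
  if (length(rooti) == 0L) stopf("%s: no root node (parent -1)", path)
  if (length(rooti) > 1L) {
    stopf("%s: multiple root nodes on lines %s", path,
          paste(lineno[rooti], collapse = ", "))
  }
  pidx <- match(parent, ids)
  dangling <- which(parent != -1L & is.na(pidx))
  if (length(dangling) > 0L) {
    stopf("%s: line %d references missing parent id %d", path,
          lineno[dangling[1L]], parent[dangling[1L]])
  }
  xyz <- tab[, 3:5, drop = FALSE]
  # collapse nodes that coincide with their parent (zero-length links)
  remap <- seq_len(nrow(tab))
  dup <- rep(FALSE, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    p <- pidx[i]
    if (!is.na(p) && all(xyz[i, ] == xyz[p, ])) {
      dup[i] <- TRUE
      remap[i] <- remap[p]
    }
  }
  if (any(dup)) {
    warnf("%s: collapsed %d node(s) duplicating their parent's coordinates",
          path, sum(dup))
  }
  keepnode <- !dup
  newid <- cumsum(keepnode)
  vmap <- newid[remap]
  verts <- xyz[keepnode, , drop = FALSE]
  child <- which(parent != -1L & keepnode)
  edges <- cbind(vmap[pidx[child]], vmap[child])
  if (nrow(edges) == 0L) stopf("%s: morphology has no segments", path)
  build_network(verts, edges, root = vmap[rooti])
}

#' Write a network to an SWC file
#'
#' Nodes are emitted in depth-first order from the root; the radius column
#' (unused by the analysis) is written as a 0.5 placeholder, type code 1 for
#' the root and 3 (basal dendrite) otherwise.
#'
#' @param net a rooted `linnet3d`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(net, path) {
  if (is.null(net$root)) stopf("cannot write an unrooted network to SWC")
  nv <- nrow(net$vertices)
  adj <- vector("list", nv)
  for (e in seq_len(nrow(net$edges))) {
    a <- net$edges[e, 1L]; b <- net$edges[e, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  order <- integer(nv)
  parent <- integer(nv)
  seen <- rep(FALSE, nv)
  stack <- net$root
  pstack <- 0L
  k <- 0L
  while (length(stack) > 0L) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    p <- pstack[length(pstack)]; pstack <- pstack[-length(pstack)]
    if (seen[v]) next
    seen[v] <- TRUE
    k <- k + 1L
    order[k] <- v
    parent[v] <- p
    nb <- adj[[v]][!seen[adj[[v]]]]
    stack <- c(stack, rev(nb))
    pstack <- c(pstack, rep.int(v, length(nb)))
  }
  newid <- integer(nv)
  newid[order] <- seq_len(nv)
  lines <- c("# generated by netdendro::write_swc",
             "# id type x y z radius parent")
  body <- vapply(seq_len(nv), function(i) {
    v <- order[i]
    p <- parent[v]
    sprintf("%d %d %.9g %.9g %.9g 0.5 %d",
            i, if (p == 0L) 1L else 3L,
            net$vertices[v, 1L], net$vertices[v, 2L], net$vertices[v, 3L],
            if (p == 0L) -1L else newid[p])
  }, character(1L))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read event locations from a CSV file
#'
#' Accepts either `x,y,z` coordinates in micrometres (snapped onto the
#' network via [snap_to_network()]) or already-networked `segment,offset`
#' rows (validated directly; 1-based segment ids).
#'
#' @param path CSV file with one of the two headers.
#' @param net the `linnet3d` the events live on.
#' @param max_snap maximum Euclidean snapping residual (um) for xyz input.
#' @return a `netppp`.
#' @export
read_events <- function(path, net, max_snap = 5) {
  tab <- utils::read.csv(path)
  cols <- tolower(names(tab))
  if (all(c("x", "y", "z") %in% cols)) {
    p <- as.matrix(tab[, match(c("x", "y", "z"), cols)])
    loc <- snap_to_network(net, p, max_dist = max_snap)
  } else if (all(c("segment", "offset") %in% cols)) {
    seg <- tab[[match("segment", cols)]]
    off <- tab[[match("offset", cols)]]
    loc <- tryCatch(canonical_locs(net, netloc(seg, off)), error = function(e) {
      len <- net$lengths[pmin(pmax(as.integer(seg), 1L), nrow(net$edges))]
      bad <- which(seg < 1 | seg > nrow(net$edges) | off < 0 | off > len)[1L]
      stopf("%s: invalid (segment, offset) on data row %d: %s", path,
            if (is.na(bad)) NA_integer_ else bad, conditionMessage(e))
    })
  } else {
    stopf("%s: header must be x,y,z or segment,offset", path)
  }
  net_pattern(net, loc)
}

#' Write event locations to a CSV file
#'
#' Events are written as `segment,offset` rows (the exact on-network
#' representation; round-trips through [read_events()] losslessly).
#'
#' @param pattern a `netppp`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(pattern, path) {
  utils::write.csv(data.frame(segment = pattern$loc$seg, offset = pattern$loc$offset),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a summary function (or envelope) to a CSV file
#'
#' @param x a `netsumfun` or `envelope_test`.
#' @param path output CSV path; columns `d,value,theoretical` plus
#'   `lower,upper` for envelopes.
#' @return `path`, invisibly.
#' @export
write_curve <- function(x, path) {
  tab <- if (inherits(x, "envelope_test")) x$curves else
    as.data.frame(x)[, c("d", "value", "theoretical")]
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Descriptive statistics of a network point pattern
#'
#' The per-dendrite summary used to characterise reconstructions: event count
#' `n`, total network length `|L|`, mean intensity `n/|L|`, circumradius `R`,
#' and the number of branching points (vertices of degree at least 3).
#'
#' @param net a `linnet3d`.
#' @param pattern a `netppp` on `net` (may be omitted to describe the bare
#'   network with `n = 0`).
#' @return class `describe_record`.
#' @export
describe <- function(net, pattern = NULL) {
  n <- if (is.null(pattern)) 0L else pattern$n
  describe_record(n = n,
                  total_length = net$total_length,
                  circumradius = circumradius(net),
                  branch_points = sum(net$degree >= 3L))
}

#' Construct a descriptive-statistics record
#'
#' Useful for assembling records from published tables as well as from
#' [describe()].
#'
#' @param n event count.
#' @param total_length network length in micrometres.
#' @param circumradius circumradius in micrometres.
#' @param branch_points number of branching points.
#' @param mean_intensity events/um; computed as `n / total_length` by default.
#' @return class `describe_record` (also a one-row data frame).
#' @export
describe_record <- function(n, total_length, circumradius, branch_points,
                            mean_intensity = n / total_length) {
  out <- data.frame(n = n, total_length = total_length,
                    mean_intensity = mean_intensity,
                    circumradius = circumradius, branch_points = branch_points)
  class(out) <- c("describe_record", "data.frame")
  out
}

#' Column means of a set of descriptive records
#'
#' Reproduces the "Mean" row of a descriptive table: the plain column mean of
#' each statistic (the intensity column is the mean of the per-record
#' ratios, not the pooled ratio).
#'
#' @param records a list of `describe_record` objects (or a data frame of
#'   stacked records).
#' @return a `describe_record` of column means.
#' @export
describe_mean <- function(records) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- do.call(rbind, records)
  }
  m <- colMeans(records)
  describe_record(n = m[["n"]], total_length = m[["total_length"]],
                  circumradius = m[["circumradius"]],
                  branch_points = m[["branch_points"]],
                  mean_intensity = m[["mean_intensity"]])
}

#' @export
print.describe_record <- function(x, ...) {
  cat(sprintf("n = %g, |L| = %.2f um, n/|L| = %.2f events/um, R = %.2f um, #BP = %g\n",
              x$n, x$total_length, x$mean_intensity, x$circumradius, x$branch_points))
  invisible(x)
}
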