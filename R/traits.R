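#' Extract the RSA trait vector from a mask and skeleton
#'
#' Computes the full seedling root-system-architecture trait set from a
#' segmented binary mask and its skeleton. Lengths are skeleton
#' edge-weighted path lengths (1 per orthogonal step, sqrt(2) per diagonal)
#' converted to cm; areas come from mask pixel counts and the convex hull;
#' the primary root is traced as the maximal-depth geodesic from the
#' top-most skeleton node, which matches taproot morphology. Depth bands
#' ("upper one-third" / "lower two-thirds") are defined on the depth extent
#' of the root system itself, not the image frame.
#'
#' Traits with undefined values on a given root (e.g. lateral-root angle
#' when there are no laterals, LED when the lower band is empty) are
#' returned as NA, never zero.
#'
#' @param mask a `binary_mask` from [segment_root()].
#' @param skeleton a `skeleton` from [skeletonize_mask()]; computed from
#'   the mask when omitted.
#' @param day imaging day (used only to annotate the result).
#' @param angle_probe_px how far along a lateral its emergence direction is
#'   measured (default 20 px).
#' @return one-row data.frame of named traits (units: cm, cm^2, cm^3,
#'   degrees, counts, ratios).
#' @export
extract_traits <- function(mask, skeleton = NULL, day = NA,
                           angle_probe_px = 20) {
  m <- mask$mask; scale <- mask$px_per_cm
  if (is.null(skeleton)) skeleton <- skeletonize_mask(mask)
  sk <- skeleton$mask
  if (!any(sk)) stop_param("empty skeleton")
  g <- skeleton_graph(sk)
  px <- g$pixels
  rows_fg <- which(rowSums(m) > 0); cols_fg <- which(colSums(m) > 0)
  rmin <- min(rows_fg); rmax <- max(rows_fg)
  depth_px <- rmax - rmin + 1
  DEP <- depth_px / scale
  WID <- (max(cols_fg) - min(cols_fg) + 1) / scale
  WDR <- WID / DEP

  TRL <- sum(g$weights) / scale

  # primary root: geodesic from top-most node to the deepest reachable node
  top <- which(px[, 1] == min(px[, 1]))
  top <- top[which.min(abs(px[top, 2] - mean(px[, 2])))]
  dists <- igraph::distances(g$graph, v = top)[1, ]
  reach <- which(is.finite(dists))
  deepest <- reach[which.max(px[reach, 1] + 1e-9 * dists[reach])]
  PRL <- dists[deepest] / scale
  path_v <- as.integer(igraph::shortest_paths(g$graph, from = top,
                                              to = deepest)$vpath[[1]])
  SRL <- TRL - PRL

  # laterals: skeleton edges leaving the primary path
  on_path <- rep(FALSE, nrow(px)); on_path[path_v] <- TRUE
  el <- g$edges
  departing <- xor(on_path[el[, 1]], on_path[el[, 2]])
  LRB <- sum(departing)
  dep_el <- el[departing, , drop = FALSE]
  NLR <- length(unique(ifelse(on_path[dep_el[, 1]], dep_el[, 1], dep_el[, 2])))
  angles <- lateral_angles(g, on_path, departing, angle_probe_px)
  LRA <- if (length(angles)) stats::median(angles) else NA_real_

  # band split on the root's own depth extent
  band <- rmin + depth_px / 3
  mid_r <- (px[el[, 1], 1] + px[el[, 2], 1]) / 2
  TRLUpper <- sum(g$weights[mid_r < band]) / scale
  TRLLower <- sum(g$weights[mid_r >= band]) / scale
  LED <- if (TRLLower > 0) TRLUpper / TRLLower else NA_real_

  NWA <- sum(m) / scale^2
  CVA <- convex_area_px(m) / scale^2
  SOL <- if (CVA > 0) NWA / CVA else NA_real_
  SOL2 <- if (!is.na(SOL) && SOL > 0) 1 / SOL else NA_real_

  pix <- which(m, arr.ind = TRUE)
  TRArea <- NWA
  TRAUpper <- sum(pix[, 1] < band) / scale^2
  TRALower <- TRArea - TRAUpper

  outline <- extract_outline(mask)
  pp <- outline$points
  PER <- sum(sqrt(rowSums((pp - pp[c(2:nrow(pp), 1), ])^2))) / scale

  dm <- distance_map(m)
  radius_px <- pmax(dm[sk] - 0.5, 0.5)
  DIA <- mean(2 * radius_px) / scale

  # primary-root corridor: radius sampled along the path
  path_px <- px[path_v, , drop = FALSE]
  if (nrow(path_px) >= 2) {
    step <- sqrt(rowSums((path_px[-1, , drop = FALSE] -
                          path_px[-nrow(path_px), , drop = FALSE])^2))
    r_path <- pmax(dm[cbind(path_px[, 1], path_px[, 2])] - 0.5, 0.5)
    r_mid <- (r_path[-1] + r_path[-length(r_path)]) / 2
    VOL <- sum(pi * (r_mid / scale)^2 * step / scale)
    PRA <- sum(2 * (r_mid / scale) * step / scale)
  } else { VOL <- NA_real_; PRA <- NA_real_ }

  rhzo_mask <- dilate_disc(m, radius_px = 0.2 * scale)
  RHZO <- sum(rhzo_mask) / scale^2

  crossings <- row_crossings(m)
  MED <- stats::median(crossings); MAX <- max(crossings)
  BSH <- if (MED > 0) MAX / MED else NA_real_

  SRL_PRL <- if (PRL > 0) LRB / PRL else NA_real_
  SRL_LRB <- if (LRB > 0) SRL / LRB else NA_real_
  MSL <- SRL_LRB

  cg <- centroid_ratios(m, rmin, depth_px)

  data.frame(day = day, TRL = TRL, PRL = PRL, SRL = SRL, DEP = DEP,
             WID = WID, WDR = WDR, CVA = CVA, NWA = NWA, SOL = SOL,
             SOL2 = SOL2, TRLUpper = TRLUpper, TRLLower = TRLLower,
             LED = LED, TRArea = TRArea, TRAUpper = TRAUpper,
             TRALower = TRALower, PRA = PRA, PER = PER, DIA = DIA,
             VOL = VOL, RHZO = RHZO, LRB = LRB, IRB = LRB, NLR = NLR,
             MED = MED, MAX = MAX, BSH = BSH, SRL_PRL = SRL_PRL,
             SRL_LRB = SRL_LRB, MSL = MSL, LRA = LRA,
             COM = cg$COM, COP = cg$COP, CMT = cg$CMT, CMM = cg$CMM,
             CMB = cg$CMB, CPT = cg$CPT, CPM = cg$CPM, CPB = cg$CPB)
}

# 8-connected skeleton graph; redundant diagonals (short-cutting an
# existing orthogonal corner) are dropped so path lengths are not
# double-counted
skeleton_graph <- function(sk) {
  px <- which(sk, arr.ind = TRUE)
  id <- matrix(0L, nrow(sk), ncol(sk))
  id[px] <- seq_len(nrow(px))
  edges <- NULL; weights <- NULL
  at <- function(r, c) {
    ok <- r >= 1 & r <= nrow(sk) & c >= 1 & c <= ncol(sk)
    out <- integer(length(r)); out[ok] <- id[cbind(r[ok], c[ok])]; out
  }
  r <- px[, 1]; c <- px[, 2]
  for (off in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    nb <- at(r + off[1], c + off[2])
    keep <- nb > 0
    if (all(off != 0) && any(keep)) {
      # diagonal: redundant if an orthogonal common neighbour exists
      redund <- at(r, c + off[2]) > 0 | at(r + off[1], c) > 0
      keep <- keep & !redund
    }
    if (any(keep)) {
      edges <- rbind(edges, cbind(id[cbind(r, c)][keep], nb[keep]))
      weights <- c(weights, rep(sqrt(sum(off^2)), sum(keep)))
    }
  }
  gr <- igraph::make_empty_graph(n = nrow(px), directed = FALSE)
  if (!is.null(edges))
    gr <- igraph::add_edges(gr, t(edges), weight = weights)
  list(graph = gr, pixels = px,
       edges = if (is.null(edges)) matrix(0L, 0, 2) else edges,
       weights = if (is.null(weights)) numeric(0) else weights)
}

lateral_angles <- function(g, on_path, departing, probe_px) {
  if (!any(departing)) return(numeric(0))
  el <- g$edges; px <- g$pixels
  # sever the primary path so geodesics from each attachment stay on the
  # lateral; the attachment vertex itself is kept as the walk's origin
  path_edge <- on_path[el[, 1]] & on_path[el[, 2]]
  g2 <- igraph::delete_edges(g$graph, which(path_edge))
  attach <- ifelse(on_path[el[, 1]], el[, 1], el[, 2])[departing]
  other <- ifelse(on_path[el[, 1]], el[, 2], el[, 1])[departing]
  ua <- unique(attach)
  D <- igraph::distances(g2, v = ua)
  angs <- numeric(length(attach))
  for (i in seq_along(attach)) {
    d <- D[match(attach[i], ua), ]
    cand <- which(is.finite(d) & d <= probe_px & !on_path)
    tip <- if (length(cand)) cand[which.max(d[cand])] else other[i]
    dvec <- px[tip, ] - px[attach[i], ]
    ang <- atan2(abs(dvec[2]), dvec[1]) * 180 / pi
    angs[i] <- min(max(ang, 0), 90)
  }
  angs
}

convex_area_px <- function(m) {
  pts <- which(m, arr.ind = TRUE)
  hull1 <- grDevices::chull(pts[, 2], pts[, 1])
  hp <- pts[hull1, , drop = FALSE]
  # expand hull pixels to their corners so filled convex shapes have
  # hull area equal to their pixel area
  corners <- rbind(cbind(hp[, 1] - 0.5, hp[, 2] - 0.5),
                   cbind(hp[, 1] - 0.5, hp[, 2] + 0.5),
                   cbind(hp[, 1] + 0.5, hp[, 2] - 0.5),
                   cbind(hp[, 1] + 0.5, hp[, 2] + 0.5))
  h2 <- grDevices::chull(corners[, 2], corners[, 1])
  cc <- corners[h2, , drop = FALSE]
  abs(polygon_area_signed(cc[, 2], cc[, 1]))
}

distance_map <- function(m) {
  dm <- EBImage::distmap(EBImage::Image(t(m + 0)))
  t(matrix(as.numeric(EBImage::imageData(dm)), ncol(m), nrow(m)))
}

dilate_disc <- function(m, radius_px) {
  dm <- distance_map(!m)
  m | (dm <= radius_px & dm > 0)
}

row_crossings <- function(m) {
  counts <- apply(m, 1, function(row) sum(diff(c(FALSE, row)) == 1))
  counts[counts > 0]
}

centroid_ratios <- function(m, rmin, depth_px) {
  pix_r <- which(m, arr.ind = TRUE)[, 1]
  occ_r <- sort(unique(pix_r))
  rel <- function(r) (mean(r) - rmin + 0.5) / depth_px
  b1 <- rmin + depth_px / 3; b2 <- rmin + 2 * depth_px / 3
  band_of <- function(r) findInterval(r, c(b1, b2)) + 1L
  com_band <- function(b) {
    r <- pix_r[band_of(pix_r) == b]
    if (length(r)) rel(r) else NA_real_
  }
  cop_band <- function(b) {
    r <- occ_r[band_of(occ_r) == b]
    if (length(r)) rel(r) else NA_real_
  }
  list(COM = rel(pix_r), COP = rel(occ_r),
       CMT = com_band(1), CMM = com_band(2), CMB = com_band(3),
       CPT = cop_band(1), CPM = cop_band(2), CPB = cop_band(3))
}

#' Add total-root-length growth rates to a trait table
#'
#' TRL_GR at day t is (TRL_t - TRL_prev) / (t - prev) in cm/day, using the
#' previous imaging day for the same (genotype, replicate); the first
#' imaging day is baselined against zero length at germination (day 0).
#' Missing earlier days give missing growth rates, not zeros.
#'
#' @param table long TraitTable with trait "TRL" rows (columns genotype,
#'   replicate, day, trait, value).
#' @param schedule the study's imaging-day schedule (default c(6, 9, 12));
#'   the earliest scheduled day is baselined against zero length at
#'   germination, later days against the preceding scheduled day.
#' @return the table with "TRL_GR" rows appended.
#' @export
compute_growth_rates <- function(table, schedule = c(6, 9, 12)) {
  trl <- table[table$trait == "TRL", , drop = FALSE]
  if (!nrow(trl)) stop_param("table contains no TRL rows")
  sched <- sort(unique(schedule))
  key <- interaction(trl$genotype, trl$replicate, drop = TRUE)
  out <- lapply(split(trl, key), function(d) {
    d <- d[order(d$day), , drop = FALSE]
    prev_day <- c(0, d$day[-nrow(d)])
    prev_trl <- c(0, d$value[-nrow(d)])
    gr <- (d$value - prev_trl) / (d$day - prev_day)
    # the rate is defined only against the scheduled predecessor; a
    # missing earlier imaging day leaves it missing
    expected_prev <- c(0, sched)[match(d$day, sched)]
    gr[is.na(expected_prev) | prev_day != expected_prev] <- NA_real_
    transform(d, trait = "TRL_GR", value = gr)
  })
  rbind(table, do.call(rbind, c(out, make.row.names = FALSE)))
}
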