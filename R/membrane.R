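#' Area decomposition of a mixed phospholipid/cholesterol bilayer
#'
#' Decomposes the box area into per-species cross-sectional areas from the
#' lipid volume balance:
#' \deqn{A_{Chol} = 2 A_{box} V_{Chol} / (V_{box} - N_W V_W)}
#' \deqn{A_{PL} = \frac{2 A_{box} (V_{box} - N_W V_W - x N V_{Chol})}
#'                     {(V_{box} - N_W V_W)(1 - x) N}}
#' so that \eqn{(1-x) N A_{PL} + x N A_{Chol} = 2 A_{box}} holds exactly.
#' The instantaneous area per lipid is the box area over the lipids per
#' monolayer.
#'
#' @param frame A `membrane_frame` (see [gen_membrane_frame()]) or any list
#'   with fields `a_box`, `v_box`, `n_water`, `n_lipid`, `x_chol`,
#'   `v_water`, `v_chol`.
#' @return Object of class `area_result`: `a_pl`, `a_chol`, `a_inst`
#'   (all nm^2).
#' @export
area_decomposition <- function(frame) {
  need <- c("a_box", "v_box", "n_water", "n_lipid", "x_chol")
  if (!all(need %in% names(frame))) stop("frame lacks fields: ",
                                         paste(setdiff(need, names(frame)), collapse = ", "))
  vw <- frame$v_water %||% 0.0312
  vc <- frame$v_chol %||% 0.593
  x <- frame$x_chol
  n <- frame$n_lipid
  vl <- frame$v_box - frame$n_water * vw
  if (vl <= 0) stop("implied lipid volume is non-positive")
  if (x >= 1) stop("x_chol = 1: no phospholipid present, A_PL undefined")
  a_chol <- 2 * frame$a_box * vc / vl
  num <- vl - x * n * vc
  if (num <= 0) stop("implied phospholipid volume is negative")
  a_pl <- 2 * frame$a_box * num / (vl * (1 - x) * n)
  structure(list(a_pl = a_pl, a_chol = a_chol, a_inst = frame$a_box / (n / 2)),
            class = "area_result")
}

#' @export
print.area_result <- function(x, ...) {
  cat(sprintf("Areas: A_PL = %.4f nm^2, A_Chol = %.4f nm^2, instant area per lipid = %.4f nm^2\n",
              x$a_pl, x$a_chol, x$a_inst))
  invisible(x)
}

#' Deuterium order parameter of C-D vectors
#'
#' S_CD = (3 cos^2 theta - 1)/2 per vector, theta being the angle to the
#' bilayer normal. Bounded in `[-0.5, 1]`: 1 for vectors parallel to the
#' normal, -0.5 perpendicular, 0 at the magic angle (54.7356 deg) and for
#' isotropic orientations on average.
#'
#' @param vectors n x 3 matrix of C-D vectors (any nonzero length).
#' @param normal Bilayer normal (default +z).
#' @return Numeric vector of per-vector S_CD values.
#' @export
order_parameter <- function(vectors, normal = c(0, 0, 1)) {
  vectors <- rbind(vectors)
  nn <- sqrt(sum(normal^2))
  if (nn == 0) stop("zero-length normal")
  vn <- sqrt(rowSums(vectors^2))
  if (any(vn == 0)) stop("zero-length chain vector")
  cost <- as.numeric(vectors %*% normal) / (vn * nn)
  unname((3 * cost^2 - 1) / 2)
}

#' Per-carbon deuterium order parameter profile
#'
#' Averages [order_parameter()] over all C-D vectors sharing a carbon index.
#'
#' @param frame A `membrane_frame` with `chain_vectors`, `carbon_index` and
#'   `normal`.
#' @return data.frame with columns `carbon` and `s_cd`.
#' @export
order_parameter_profile <- function(frame) {
  s <- order_parameter(frame$chain_vectors, frame$normal)
  agg <- tapply(s, frame$carbon_index, mean)
  data.frame(carbon = as.integer(names(agg)), s_cd = as.numeric(agg))
}

#' Orientation histogram of molecular axes against the bilayer normal
#'
#' Angles arccos(axis . normal) in degrees on `[0, 180]`, binned and
#' normalized to unit mass. Isotropically oriented axes follow the
#' solid-angle measure, i.e. a histogram proportional to sin(theta).
#'
#' @param axes n x 3 matrix of (unit) axis vectors.
#' @param normal Bilayer normal (default +z).
#' @param bins Number of bins (>= 2, default 36, i.e. 5-degree bins).
#' @return Object of class `orientation_histogram`: `breaks_deg`,
#'   `mid_deg`, `mass` (sums to 1), `modal_deg`, `angles_deg`.
#' @export
orientation_histogram <- function(axes, normal = c(0, 0, 1), bins = 36) {
  if (bins < 2) stop("bins must be >= 2")
  axes <- rbind(axes)
  vn <- sqrt(rowSums(axes^2))
  if (any(vn == 0)) stop("zero-length axis vector")
  nn <- sqrt(sum(normal^2))
  cost <- pmin(1, pmax(-1, as.numeric(axes %*% normal) / (vn * nn)))
  ang <- acos(cost) * 180 / pi
  breaks <- seq(0, 180, length.out = bins + 1)
  idx <- findInterval(ang, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  mass <- tabulate(idx, nbins = bins) / length(ang)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  structure(list(breaks_deg = breaks, mid_deg = mids, mass = mass,
                 modal_deg = mids[which.max(mass)], angles_deg = ang),
            class = "orientation_histogram")
}

#' Chain elongation: head-group to terminal-carbon distance
#'
#' @param frame A `membrane_frame` with the labeled positions.
#' @param head,terminal Label names (defaults `"head"`, `"Cter"`).
#' @return Euclidean distance, nm.
#' @export
chain_elongation <- function(frame, head = "head", terminal = "Cter") {
  p <- frame$labeled_positions
  for (lab in c(head, terminal))
    if (is.null(p[[lab]])) stop("missing labeled position: ", lab)
  sqrt(sum((p[[head]] - p[[terminal]])^2))
}

#' Transverse (along-normal) distance between two labeled positions
#'
#' The absolute separation projected on the bilayer normal, e.g. the P-P
#' distance between the two phosphate planes. Invariant under in-plane
#' translation of either point.
#'
#' @param frame A `membrane_frame`.
#' @param label_a,label_b Label names.
#' @return |z_a - z_b| along the normal, nm.
#' @export
transverse_distance <- function(frame, label_a, label_b) {
  p <- frame$labeled_positions
  for (lab in c(label_a, label_b))
    if (is.null(p[[lab]])) stop("missing labeled position: ", lab)
  n <- frame$normal / sqrt(sum(frame$normal^2))
  abs(sum((p[[label_a]] - p[[label_b]]) * n))
}

#' Geometric hydrogen-bond count
#'
#' Counts (donor, acceptor) pairs satisfying both a donor-acceptor distance
#' cutoff and a hydrogen-donor-acceptor angle cutoff. Each (donor, acceptor)
#' pair is counted at most once even if several hydrogens of the donor
#' qualify. The 0.35 nm / 30 degree defaults are the common geometric
#' criterion; both are exposed because no single definition is universal.
#'
#' @param donors n x 3 matrix of donor heavy-atom positions, nm.
#' @param hydrogens n x 3 matrix of the paired hydrogen positions (row i is
#'   the hydrogen of donor row i; repeat a donor row for multiple
#'   hydrogens).
#' @param acceptors m x 3 matrix of acceptor positions, nm.
#' @param d_cut Donor-acceptor distance cutoff, nm (default 0.35).
#' @param angle_cut Hydrogen-donor-acceptor angle cutoff, degrees
#'   (default 30).
#' @param donor_id Optional integer ids grouping donor rows that are the
#'   same physical donor (default: every row distinct).
#' @return Integer count of hydrogen-bonded (donor, acceptor) pairs.
#' @export
hbond_count <- function(donors, hydrogens, acceptors,
                        d_cut = 0.35, angle_cut = 30, donor_id = NULL) {
  donors <- rbind(donors); hydrogens <- rbind(hydrogens); acceptors <- rbind(acceptors)
  if (nrow(donors) != nrow(hydrogens))
    stop("donors and hydrogens must be paired row-by-row")
  donor_id <- donor_id %||% seq_len(nrow(donors))
  if (length(donor_id) != nrow(donors)) stop("donor_id must match the donor rows")
  hd <- hydrogens - donors
  hd_n <- sqrt(rowSums(hd^2))
  if (any(hd_n == 0)) stop("hydrogen coincides with its donor")
  cos_cut <- cos(angle_cut * pi / 180)
  pairs <- matrix(numeric(0), ncol = 2)
  for (j in seq_len(nrow(acceptors))) {
    da <- sweep(-donors, 2, acceptors[j, ], `+`)
    da_n <- sqrt(rowSums(da^2))
    ok <- da_n <= d_cut & da_n > 0 &
      rowSums(hd * da) / (hd_n * da_n) >= cos_cut
    if (any(ok)) pairs <- rbind(pairs, cbind(donor_id[ok], j))
  }
  nrow(unique(pairs))
}
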