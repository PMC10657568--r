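#' Default landmark template for shape simulation
#'
#' A 33-point scheme mimicking a hymenopteran head capsule in full-face
#' view: 13 fixed landmarks (clypeal margin, mandibular insertions, eye
#' margins, posterolateral corners, median concavity) and two lateral
#' outline curves of 10 semilandmarks each, so slider logic is
#' exercised.  The template is centered and scaled to unit centroid
#' size.
#'
#' @return list with `points` (`33 x 2`), `n_fixed` (13), and `sliders`
#'   (a [sliders_spec()] chaining each curve's semilandmarks between its
#'   anchoring fixed landmarks).
#' @export
default_template <- function() {
  # fixed landmarks on an oval head outline plus interior loci
  fixed <- rbind(
    c(0.00,  1.00),   # 1 median concavity of posterior margin
    c(-0.45, 0.95), c(0.45, 0.95),    # 2,3 posterolateral corners
    c(-0.62, 0.35), c(0.62, 0.35),    # 4,5 upper eye margins
    c(-0.55, -0.05), c(0.55, -0.05),  # 6,7 lower eye margins
    c(-0.35, -0.85), c(0.35, -0.85),  # 8,9 mandibular insertions
    c(0.00, -0.95),                   # 10 anterior clypeal midpoint
    c(-0.18, -0.55), c(0.18, -0.55),  # 11,12 clypeal disc corners
    c(0.00, -0.35))                   # 13 clypeal disc midpoint
  curve_t <- seq(0.12, 0.88, length.out = 10L)
  left  <- cbind(-0.62 - 0.10 * sin(pi * curve_t), 0.90 - 1.70 * curve_t)
  right <- cbind(0.62 + 0.10 * sin(pi * curve_t), 0.90 - 1.70 * curve_t)
  pts <- rbind(fixed, left, right)
  pts <- center_config(pts) / centroid_size(pts)
  # curves run 2 -> (14..23) -> 8 and 3 -> (24..33) -> 9
  chain <- function(first, idx, last) {
    nb <- c(first, idx[-length(idx)])
    na <- c(idx[-1L], last)
    cbind(nb, idx, na)
  }
  trip <- rbind(chain(2L, 14:23, 8L), chain(3L, 24:33, 9L))
  list(points = pts, n_fixed = 13L, sliders = sliders_spec(trip, 33L))
}

#' Specify a synthetic labelled shape dataset
#'
#' Defines the ground-truth structure of a simulated landmark dataset:
#' per-species mean displacement fields applied to a common template,
#' additive site effects nested in species, isotropic per-landmark
#' specimen variation, small replicate (digitization) error, and
#' per-configuration nuisance rotation, translation and scale that the
#' superimposition must remove.  Species and site displacement fields
#' are drawn once per dataset as smooth low-bending-energy thin-plate
#' spline deformations of the template, so synthetic species differ the
#' way biological shapes do rather than by white-noise offsets.
#'
#' @param n_species number of species (default 2).
#' @param n_sites sites per species (default 2).
#' @param n_specimens specimens per species-site combination (default 5).
#' @param n_replicates digitization replicates per specimen (default 2).
#' @param species_scale RMS magnitude of the per-species mean
#'   displacement field, in units of template centroid size
#'   (default 0.02).
#' @param site_scale RMS magnitude of per-site displacement fields
#'   (default 0.01).
#' @param sigma isotropic per-landmark specimen noise sd (default 0.005).
#' @param sigma_rep replicate (digitization) noise sd (default 0.001).
#' @param rotation_range nuisance rotation range in radians
#'   (default `c(0, 2 * pi)`).
#' @param translation_range nuisance translation range per axis
#'   (default `c(-1, 1)`).
#' @param scale_range nuisance scale factor range (default `c(0.5, 2)`).
#' @param template template list as from [default_template()].
#' @param seed integer seed fixing the dataset bit-for-bit.
#' @return object of class `shape_sim_spec` (a list of the above).
#' @export
shape_sim_spec <- function(n_species = 2L, n_sites = 2L, n_specimens = 5L,
                           n_replicates = 2L, species_scale = 0.02,
                           site_scale = 0.01, sigma = 0.005,
                           sigma_rep = 0.001,
                           rotation_range = c(0, 2 * pi),
                           translation_range = c(-1, 1),
                           scale_range = c(0.5, 2),
                           template = default_template(), seed = 1L) {
  stopifnot(n_species >= 1L, n_sites >= 1L, n_specimens >= 1L,
            n_replicates >= 1L, sigma >= 0, sigma_rep >= 0,
            species_scale >= 0, site_scale >= 0,
            scale_range[1L] > 0)
  if (nrow(template$points) < 3L) stop("template needs k >= 3 landmarks")
  structure(list(n_species = n_species, n_sites = n_sites,
                 n_specimens = n_specimens, n_replicates = n_replicates,
                 species_scale = species_scale, site_scale = site_scale,
                 sigma = sigma, sigma_rep = sigma_rep,
                 rotation_range = rotation_range,
                 translation_range = translation_range,
                 scale_range = scale_range, template = template,
                 seed = as.integer(seed)),
            class = "shape_sim_spec")
}

# A smooth random displacement field over the template: a thin-plate
# spline from a coarse control grid to randomly displaced targets,
# evaluated at the template points, centered, and rescaled to the
# requested RMS magnitude.
random_displacement_field <- function(points, scale) {
  if (scale <= 0) return(matrix(0, nrow(points), 2L))
  rx <- range(points[, 1L]); ry <- range(points[, 2L])
  gx <- seq(rx[1L] - 0.1 * diff(rx), rx[2L] + 0.1 * diff(rx), length.out = 3L)
  gy <- seq(ry[1L] - 0.1 * diff(ry), ry[2L] + 0.1 * diff(ry), length.out = 3L)
  ctrl <- as.matrix(expand.grid(gx, gy))
  disp <- matrix(stats::rnorm(nrow(ctrl) * 2L, sd = 0.05 * diff(rx)),
                 ncol = 2L)
  warp <- fit_tps(ctrl, ctrl + disp)
  field <- warp_points(warp, points) - points
  field <- sweep(field, 2L, colMeans(field))
  rms <- sqrt(mean(field^2))
  if (rms == 0) return(field)
  field * scale / rms
}

#' Simulate a labelled landmark dataset with known ground truth
#'
#' Each digitized configuration is built as
#' `nuisance(template + species effect + site effect + specimen noise
#' + replicate noise)`, with a complete label table (`species`, `site`,
#' `colony`, `replicate_id`) emitted alongside.  The same seed
#' reproduces the dataset bit-for-bit.
#'
#' @param spec a [shape_sim_spec()].
#' @return a [shape_dataset()] with labels; the slider specification of
#'   the template is attached as attribute `"sliders"` and the spec as
#'   attribute `"spec"`.
#' @export
simulate_shapes <- function(spec) {
  stopifnot(inherits(spec, "shape_sim_spec"))
  tpl <- spec$template$points
  k <- nrow(tpl)
  withr::with_seed(spec$seed, {
    sp_eff <- lapply(seq_len(spec$n_species), function(s)
      random_displacement_field(tpl, spec$species_scale))
    site_eff <- lapply(seq_len(spec$n_species), function(s)
      lapply(seq_len(spec$n_sites), function(t)
        random_displacement_field(tpl, spec$site_scale)))
    n_total <- spec$n_species * spec$n_sites * spec$n_specimens *
      spec$n_replicates
    coords <- array(0, dim = c(k, 2L, n_total))
    lab <- data.frame(id = character(n_total), species = "", site = "",
                      colony = "", replicate_id = "",
                      stringsAsFactors = FALSE)
    idx <- 0L
    for (s in seq_len(spec$n_species)) for (t in seq_len(spec$n_sites)) {
      for (i in seq_len(spec$n_specimens)) {
        specimen <- tpl + sp_eff[[s]] + site_eff[[s]][[t]] +
          matrix(stats::rnorm(2L * k, sd = spec$sigma), k, 2L)
        for (r in seq_len(spec$n_replicates)) {
          cfg <- specimen +
            matrix(stats::rnorm(2L * k, sd = spec$sigma_rep), k, 2L)
          th <- stats::runif(1L, spec$rotation_range[1L],
                             spec$rotation_range[2L])
          sc <- stats::runif(1L, spec$scale_range[1L], spec$scale_range[2L])
          tr <- stats::runif(2L, spec$translation_range[1L],
                             spec$translation_range[2L])
          R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
          cfg <- sc * cfg %*% R
          cfg[, 1L] <- cfg[, 1L] + tr[1L]
          cfg[, 2L] <- cfg[, 2L] + tr[2L]
          idx <- idx + 1L
          coords[, , idx] <- cfg
          lab$id[idx] <- sprintf("sp%d_st%d_i%d_r%d", s, t, i, r)
          lab$species[idx] <- paste0("sp", s)
          lab$site[idx] <- paste0("site", t)
          lab$colony[idx] <- sprintf("sp%d_st%d_i%d", s, t, i)
          lab$replicate_id[idx] <- paste0("r", r)
        }
      }
    }
  })
  ds <- shape_dataset(coords, ids = lab$id, labels = lab)
  attr(ds, "sliders") <- spec$template$sliders
  attr(ds, "spec") <- spec
  ds
}

#' Specify a synthetic aligned barcode dataset
#'
#' Ground truth for [simulate_sequences()]: group ancestors are placed
#' so that the expected realized mean p-distance between members of two
#' groups matches the target divergence, accounting for the extra
#' apparent divergence contributed by within-group mutation.
#'
#' @param between target between-group mean p-distances: a symmetric
#'   matrix with zero diagonal, or a single value applied to every pair.
#' @param n_groups number of groups (required when `between` is scalar).
#' @param within per-sequence mutation rate from the group ancestor
#'   (members of one group then differ by about twice this rate).
#' @param length_bp alignment length (default 313, a standard metazoan
#'   COI minibarcode).
#' @param group_sizes sequences per group (single value or vector).
#' @param feasibility_tol maximum tolerated least-squares residual when
#'   placing group ancestors on a star (default 0.005); target matrices
#'   violating additivity beyond this are rejected.
#' @param seed integer seed.
#' @return object of class `seq_sim_spec`.
#' @export
seq_sim_spec <- function(between, n_groups = NULL, within = 0.005,
                         length_bp = 313L, group_sizes = 10L,
                         feasibility_tol = 0.005, seed = 1L) {
  if (is.matrix(between)) {
    n_groups <- nrow(between)
    if (!isSymmetric(unname(between)) || any(diag(between) != 0))
      stop("'between' must be symmetric with zero diagonal")
  } else {
    if (is.null(n_groups)) stop("'n_groups' required when 'between' is scalar")
    between <- matrix(between, n_groups, n_groups)
    diag(between) <- 0
  }
  if (any(between < 0 | between > 0.75))
    stop("divergences must lie in [0, 0.75]")
  if (within < 0 || within > 0.75) stop("'within' must lie in [0, 0.75]")
  group_sizes <- rep(as.integer(group_sizes), length.out = n_groups)
  stopifnot(all(group_sizes >= 1L), length_bp >= 1L)
  structure(list(between = between, n_groups = n_groups, within = within,
                 length_bp = as.integer(length_bp),
                 group_sizes = group_sizes,
                 feasibility_tol = feasibility_tol, seed = as.integer(seed)),
            class = "seq_sim_spec")
}

# Probability that two sequences differ at a site, given per-sequence
# per-site mutation probability w, when their ancestors agree (q0) or
# disagree (q1) at that site.  Mutations pick one of the 3 other bases
# uniformly.
mismatch_probs <- function(w) {
  q0 <- 2 * w * (1 - w) + (2 / 3) * w^2
  q1 <- 1 - (2 * w * (1 - w) / 3 + (2 / 9) * w^2)
  c(q0 = q0, q1 = q1)
}

#' Simulate aligned sequences with a planted group structure
#'
#' A random root sequence is mutated into one ancestor per group at
#' disjoint sites, with per-group divergences solved by least squares on
#' the star model `d(i, j) = x_i + x_j` from the target between-group
#' distances (corrected for the apparent divergence added by
#' within-group mutation); each group's sequences are then mutated
#' independently from the group ancestor at the within-group rate.
#' Realized between-group mean p-distances match the targets in
#' expectation.
#'
#' @param spec a [seq_sim_spec()].
#' @return a [sequence_set()] with an extra `labels` element (data frame
#'   `id`, `group`) and the spec attached as attribute `"spec"`.
#' @export
simulate_sequences <- function(spec) {
  stopifnot(inherits(spec, "seq_sim_spec"))
  g <- spec$n_groups
  L <- spec$length_bp
  q <- mismatch_probs(spec$within)
  span <- q["q1"] - q["q0"]
  # ancestor divergences needed so realized distances hit the targets
  D <- (spec$between - q["q0"]) / span
  diag(D) <- 0
  if (any(D < -1e-9))
    stop("target between-group divergence below the level implied by ",
         "within-group mutation alone")
  D <- pmax(D, 0)
  x <- if (g == 1L) 0 else star_branches(D, spec$feasibility_tol)
  m <- round(x * L)
  if (sum(m) > L)
    stop("requested divergences need more than length_bp mutated sites")
  bases <- c("A", "C", "G", "T")
  withr::with_seed(spec$seed, {
    root <- sample(bases, L, replace = TRUE)
    free <- sample.int(L)          # disjoint site pool, random order
    anc <- vector("list", g)
    pos <- 0L
    for (i in seq_len(g)) {
      a <- root
      if (m[i] > 0L) {
        sites <- free[(pos + 1L):(pos + m[i])]
        pos <- pos + m[i]
        a[sites] <- vapply(a[sites], function(b)
          sample(setdiff(bases, b), 1L), character(1))
      }
      anc[[i]] <- a
    }
    seqs <- character(sum(spec$group_sizes))
    ids <- character(sum(spec$group_sizes))
    grp <- character(sum(spec$group_sizes))
    idx <- 0L
    for (i in seq_len(g)) for (j in seq_len(spec$group_sizes[i])) {
      s <- anc[[i]]
      if (spec$within > 0) {
        hit <- which(stats::runif(L) < spec$within)
        if (length(hit))
          s[hit] <- vapply(s[hit], function(b)
            sample(setdiff(bases, b), 1L), character(1))
      }
      idx <- idx + 1L
      seqs[idx] <- paste(s, collapse = "")
      ids[idx] <- sprintf("g%d_s%d", i, j)
      grp[idx] <- paste0("g", i)
    }
  })
  out <- sequence_set(seqs, ids = ids)
  out$labels <- data.frame(id = ids, group = grp, stringsAsFactors = FALSE)
  attr(out, "spec") <- spec
  out
}

# Least-squares branch lengths x_i >= 0 for the star model
# d(i, j) = x_i + x_j; errors if the target matrix cannot be realized
# additively within tolerance.
star_branches <- function(D, tol) {
  g <- nrow(D)
  pairs <- utils::combn(g, 2L)
  A <- matrix(0, ncol(pairs), g)
  A[cbind(seq_len(ncol(pairs)), pairs[1L, ])] <- 1
  A[cbind(seq_len(ncol(pairs)), pairs[2L, ])] <- 1
  d <- D[t(pairs)]
  x <- as.vector(solve_psd(crossprod(A), crossprod(A, d)))
  x <- pmax(x, 0)
  resid <- max(abs(A %*% x - d))
  if (resid > tol)
    stop("between-group divergence matrix cannot be realized on a star ",
         "within tolerance (max residual ", signif(resid, 3), "); it ",
         "violates additivity/triangle constraints")
  x
}
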