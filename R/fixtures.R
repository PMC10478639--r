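# Synthetic predicted models, confidence profiles and PAE matrices with a
# planted domain architecture, so that conversion, pruning, splitting and
# scoring are all testable offline with a known ground truth.
#
# Geometry is deliberately minimal: a single-chain C-alpha trace in which
# each domain is a self-avoiding fixed-step random walk confined to a sphere
# around its centroid, domains are laid out on a line, and linkers are
# equilateral bridges between consecutive domains. Every virtual bond has
# exactly the `step` length. There is no secondary structure and no
# side-chain chemistry; the fixtures emulate the block statistics of real
# predictions (high pLDDT / low intra-domain PAE inside domains, low pLDDT /
# high PAE across them), nothing more.

#' Specification of a synthetic multi-domain fixture
#'
#' @param n_domains Number of planted domains (>= 1).
#' @param domain_sizes Residues per domain (recycled to `n_domains`).
#' @param linker_lengths Residues in each inter-domain linker (recycled to
#'   `n_domains - 1`).
#' @param separation Distance in Angstroms between consecutive domain
#'   centroids (default 50).
#' @param step Virtual C-alpha bond length in Angstroms (default 3.8).
#' @param domain_plddt,domain_plddt_sd Mean and s.d. of per-residue pLDDT in
#'   domains (default 90 +- 3).
#' @param linker_plddt,linker_plddt_sd Mean and s.d. of linker pLDDT
#'   (default 45 +- 5).
#' @param pae_intra,pae_intra_sd Mean and s.d. in Angstroms of PAE entries
#'   within a domain (default 2 +- 0.5).
#' @param pae_inter,pae_inter_sd Mean and s.d. in Angstroms of PAE entries
#'   across domains or involving linkers (default 25 +- 3).
#' @param seed Integer seed; all draws derive from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_domains = 2, domain_sizes = 60,
                           linker_lengths = 10, separation = 50, step = 3.8,
                           domain_plddt = 90, domain_plddt_sd = 3,
                           linker_plddt = 45, linker_plddt_sd = 5,
                           pae_intra = 2, pae_intra_sd = 0.5,
                           pae_inter = 25, pae_inter_sd = 3, seed = 1) {
  if (n_domains < 1) mr_abort("malformed input: n_domains must be >= 1")
  domain_sizes <- rep_len(as.integer(domain_sizes), n_domains)
  linker_lengths <- rep_len(as.integer(linker_lengths), max(0, n_domains - 1))
  if (any(domain_sizes < 1)) mr_abort("malformed input: domain sizes must be >= 1")
  if (length(linker_lengths) && any(linker_lengths < 0)) {
    mr_abort("malformed input: linker lengths must be >= 0")
  }
  sds <- c(domain_plddt_sd, linker_plddt_sd, pae_intra_sd, pae_inter_sd)
  if (any(sds < 0)) mr_abort("malformed input: standard deviations must be >= 0")
  if (separation <= 0 || step <= 0) {
    mr_abort("malformed input: separation and step must be positive")
  }
  structure(
    list(n_domains = n_domains, domain_sizes = domain_sizes,
         linker_lengths = linker_lengths, separation = separation,
         step = step, domain_plddt = domain_plddt,
         domain_plddt_sd = domain_plddt_sd, linker_plddt = linker_plddt,
         linker_plddt_sd = linker_plddt_sd, pae_intra = pae_intra,
         pae_intra_sd = pae_intra_sd, pae_inter = pae_inter,
         pae_inter_sd = pae_inter_sd, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

domain_radius <- function(size) 3 * size^(1/3)

planted_labels <- function(spec) {
  labs <- integer(0)
  for (d in seq_len(spec$n_domains)) {
    labs <- c(labs, rep(d, spec$domain_sizes[d]))
    if (d < spec$n_domains) labs <- c(labs, rep(NA_integer_, spec$linker_lengths[d]))
  }
  labs
}

rand_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# Self-avoiding fixed-step walk confined to a sphere of radius R about the
# origin, starting at (-R, 0, 0). The last `steer_tail` steps are biased
# toward the exit point (+R, 0, 0) so that the walk traverses the sphere and
# ends near the side facing the next domain.
domain_walk <- function(size, R, step, steer_tail = 0, min_sep = 3.5) {
  pts <- matrix(0, size, 3)
  pts[1, ] <- c(-R, 0, 0)
  if (size == 1) return(pts)
  exit <- c(R, 0, 0)
  for (i in 2:size) {
    steered <- steer_tail > 0 && (size - i) < steer_tail
    best <- NULL
    best_score <- -Inf
    for (try in 1:60) {
      u <- rand_unit()
      if (steered) {
        to_exit <- exit - pts[i - 1, ]
        nd <- sqrt(sum(to_exit^2))
        if (nd > 1e-9) u <- 0.75 * to_exit / nd + 0.25 * u
        u <- u / sqrt(sum(u^2))
      }
      cand <- pts[i - 1, ] + step * u
      r <- sqrt(sum(cand^2))
      lim <- if (steered) 1.2 * R else R
      if (r > lim) next
      prev <- pts[seq_len(i - 2), , drop = FALSE]
      clash <- if (nrow(prev) > 0) {
        min(sqrt(rowSums(sweep(prev, 2, cand)^2)))
      } else Inf
      score <- min(clash, min_sep)  # saturate: any non-clashing step is fine
      if (clash >= min_sep) { best <- cand; break }
      if (score > best_score) { best_score <- score; best <- cand }
    }
    if (is.null(best)) {
      # fully blocked: step back toward the centre
      dir <- -pts[i - 1, ] / max(sqrt(sum(pts[i - 1, ]^2)), 1e-9)
      best <- pts[i - 1, ] + step * dir
    }
    pts[i, ] <- best
  }
  pts
}

# Equilateral arc bridge: n_pts intermediate points between A and B with all
# (n_pts + 1) bonds exactly `step` long. Points lie on a circular arc in a
# deterministic plane through A and B.
bridge_points <- function(A, B, n_pts, step) {
  n <- n_pts + 1                       # number of bonds
  D <- sqrt(sum((B - A)^2))
  if (D > n * step + 1e-9) mr_abort("infeasible linker")
  if (n_pts == 0) {
    if (abs(D - step) > 1e-6) mr_abort("infeasible linker")
    return(matrix(numeric(0), 0, 3))
  }
  e1 <- (B - A) / D
  ref <- if (abs(e1[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  ep <- ref - sum(ref * e1) * e1
  ep <- ep / sqrt(sum(ep^2))
  if (abs(D - n * step) < 1e-9) {
    k <- seq_len(n_pts)
    return(outer(k / n, B - A) + matrix(A, n_pts, 3, byrow = TRUE))
  }
  # chord ratio: sin(n t / 2) / sin(t / 2) = D / step, root in (0, 2 pi / n)
  f <- function(t) sin(n * t / 2) / sin(t / 2) - D / step
  theta <- uniroot(f, c(1e-9, 2 * pi / n - 1e-9), tol = 1e-12)$root
  R_arc <- step / (2 * sin(theta / 2))
  h <- sqrt(max(R_arc^2 - (D / 2)^2, 0))
  M <- (A + B) / 2
  O <- M - h * ep
  phiA <- atan2(sum((A - O) * ep), sum((A - O) * e1))
  pts_at <- function(dir) {
    k <- seq_len(n_pts)
    phi <- phiA + dir * k * theta
    t(vapply(phi, function(p) O + R_arc * (cos(p) * e1 + sin(p) * ep),
             numeric(3)))
  }
  for (dir in c(1, -1)) {
    phiB <- phiA + dir * n * theta
    endp <- O + R_arc * (cos(phiB) * e1 + sin(phiB) * ep)
    if (sqrt(sum((endp - B)^2)) < 1e-6) return(pts_at(dir))
  }
  mr_abort("infeasible linker")
}

# One pass generating everything the spec describes, in the documented draw
# order: coordinates, then pLDDT, then PAE. All randomness comes from a
# single stream seeded with spec$seed.
generate_fixture_internal <- function(spec, need_pae = TRUE) {
  labs <- planted_labels(spec)
  n_total <- length(labs)
  withr::with_seed(spec$seed, {
    coords <- matrix(NA_real_, n_total, 3)
    centroids <- cbind((seq_len(spec$n_domains) - 1) * spec$separation, 0, 0)
    pos <- 1L
    prev_end <- NULL
    for (d in seq_len(spec$n_domains)) {
      size <- spec$domain_sizes[d]
      R <- domain_radius(size)
      tail_steps <- if (d < spec$n_domains) min(12L, size - 1L) else 0L
      w <- domain_walk(size, R, spec$step, steer_tail = tail_steps)
      w <- sweep(w, 2, colMeans(w))                 # centroid exactly at origin
      w <- sweep(w, 2, centroids[d, ], "+")         # then at the planted centroid
      idx <- pos:(pos + size - 1)
      coords[idx, ] <- w
      if (d > 1) {
        L <- spec$linker_lengths[d - 1]
        lpts <- bridge_points(prev_end, w[1, ], L, spec$step)
        if (L > 0) coords[(pos - L):(pos - 1), ] <- lpts
      }
      prev_end <- w[size, ]
      pos <- pos + size + if (d < spec$n_domains) spec$linker_lengths[d] else 0L
    }
    plddt <- numeric(n_total)
    for (i in seq_len(n_total)) {
      plddt[i] <- if (is.na(labs[i])) {
        rnorm(1, spec$linker_plddt, spec$linker_plddt_sd)
      } else {
        rnorm(1, spec$domain_plddt, spec$domain_plddt_sd)
      }
    }
    plddt <- pmin(pmax(plddt, 0), 100)
    pae <- NULL
    if (need_pae) {
      same <- outer(labs, labs, function(a, b) !is.na(a) & !is.na(b) & a == b)
      mu <- ifelse(same, spec$pae_intra, spec$pae_inter)
      sd <- ifelse(same, spec$pae_intra_sd, spec$pae_inter_sd)
      vals <- matrix(rnorm(n_total^2, as.vector(mu), as.vector(sd)),
                     n_total, n_total)
      vals <- pmax(vals, 0)
      diag(vals) <- 0
      pae <- pae_matrix(vals, max_pae = max(31.75, ceiling(max(vals))))
    }
    list(coords = coords, plddt = plddt, labels = labs, pae = pae)
  })
}

#' Generate a synthetic predicted model with planted domains
#'
#' Produces a single-chain C-alpha-only trace: each domain is a self-avoiding
#' fixed-step walk confined to a sphere of radius `3 * size^(1/3)` Angstroms
#' about its centroid, centroids lie on a line at the spec's separation, and
#' linkers are fixed-step bridges between consecutive domains. Per-residue
#' pLDDT is drawn from the domain or linker distribution and written to the
#' B column. Fully reproducible from the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `model` (a [predicted_model]) and `truth` (a tibble of
#'   `res_index`, `domain` -- `NA` for linker residues -- and `label`).
#' @export
generate_model <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  fx <- generate_fixture_internal(spec, need_pae = FALSE)
  n <- length(fx$labels)
  atoms <- tibble(
    serial = seq_len(n), atom = "CA", alt = "", resid = "ALA", chain = "A",
    resno = seq_len(n), icode = "",
    x = fx$coords[, 1], y = fx$coords[, 2], z = fx$coords[, 3],
    occ = 1, b = round(fx$plddt, 2), element = "C"
  )
  truth <- tibble(
    res_index = seq_len(n),
    domain = fx$labels,
    label = ifelse(is.na(fx$labels), "linker", paste0("D", fx$labels))
  )
  list(
    model = predicted_model(atoms, source_tag = sprintf(
      "synthetic(n_domains=%d, seed=%d)", spec$n_domains, spec$seed)),
    truth = truth
  )
}

#' Generate the PAE matrix matching a synthetic spec
#'
#' Entry (i, j) is drawn from the intra-domain distribution when residues i
#' and j carry the same planted domain label, and from the inter-domain
#' distribution otherwise (linker residues always count as inter). The matrix
#' is generated asymmetric (independent draws for (i, j) and (j, i)) to
#' exercise downstream symmetrization; the diagonal is forced to 0 and all
#' entries are clamped non-negative.
#'
#' @param spec A [synthetic_spec()].
#' @param truth Optional planted truth (as returned by [generate_model()]);
#'   validated against the spec when supplied.
#' @return A [pae_matrix].
#' @export
generate_pae <- function(spec, truth = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  labs <- planted_labels(spec)
  if (!is.null(truth)) {
    if (nrow(truth) != length(labs) || !identical(as.integer(truth$domain),
                                                  as.integer(labs))) {
      mr_abort("label length mismatch: truth does not match spec")
    }
  }
  generate_fixture_internal(spec, need_pae = TRUE)$pae
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same residues,
#' computed from the pair-counting contingency table. 1 means identical
#' partitions (up to label renaming), 0 is the expectation for independent
#' random labelings.
#'
#' @param labels_a,labels_b Equal-length label vectors (any atomic type;
#'   `NA` is treated as its own label).
#' @return ARI value in \[-1, 1\].
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) mr_abort("label length mismatch")
  a <- addNA(factor(labels_a), ifany = TRUE)
  b <- addNA(factor(labels_b), ifany = TRUE)
  ct <- table(a, b)
  sum_ij <- sum(choose(ct, 2))
  sum_i <- sum(choose(rowSums(ct), 2))
  sum_j <- sum(choose(colSums(ct), 2))
  n2 <- choose(length(labels_a), 2)
  expected <- sum_i * sum_j / n2
  max_index <- (sum_i + sum_j) / 2
  if (abs(max_index - expected) < 1e-12) return(1)
  (sum_ij - expected) / (max_index - expected)
}
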