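# Splitting a predicted model into rigid, domain-like search models, either
# by clustering C-alpha coordinates or by community detection on the
# predicted aligned error matrix.
#
# A partition is a per-residue tibble (res_index, chain, resno, icode,
# domain) where `domain` is a 1-based id or NA for residues excluded from the
# partition. Domain ids are always renumbered by ascending first residue
# index, and every tie-break is by lower residue index / lower domain id, so
# results are deterministic.

new_domain_partition <- function(res, domain, method, params) {
  domain <- renumber_domains(domain)
  structure(
    tibble(
      res_index = res$res_index,
      chain = res$chain,
      resno = res$resno,
      icode = res$icode,
      domain = domain
    ),
    method = method,
    params = params,
    class = c("domain_partition", class(tibble()))
  )
}

renumber_domains <- function(domain) {
  present <- unique(domain[!is.na(domain)])
  ord <- present[order(vapply(present, function(d) min(which(domain == d)), 1L))]
  match(domain, ord)
}

#' @export
print.domain_partition <- function(x, ...) {
  sizes <- table(x$domain)
  cat(sprintf("<domain_partition> method=%s, %d domain(s) over %d residues",
              attr(x, "method"), length(sizes), sum(!is.na(x$domain))))
  if (any(is.na(x$domain))) cat(sprintf(" (+%d removed)", sum(is.na(x$domain))))
  cat("\n  sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  invisible(x)
}

n_domains <- function(partition) length(unique(stats::na.omit(partition$domain)))

validate_partition <- function(partition, model) {
  res <- residues(model)
  if (nrow(partition) != nrow(res)) mr_abort("length mismatch")
  if (!all(partition$res_index == res$res_index)) mr_abort("length mismatch")
  dom <- partition$domain[!is.na(partition$domain)]
  if (length(dom) > 0 && !setequal(unique(dom), seq_len(max(dom)))) {
    mr_abort("malformed input: domain ids not contiguous")
  }
  invisible(partition)
}

# CA coordinate matrix for a set of residues, rows named by res_index.
ca_coords <- function(res) {
  m <- as.matrix(res[, c("ca_x", "ca_y", "ca_z")])
  rownames(m) <- res$res_index
  m
}

#' Split a model into domains by clustering C-alpha coordinates
#'
#' Clusters the C-alpha atoms by their positions in space so that each
#' cluster is a compact, rigid unit usable as a molecular-replacement search
#' model. The default linkage is agglomerative Ward (deterministic); k-means
#' with a fixed seed is available as an alternative. Residues lacking a
#' C-alpha atom join the cluster of the nearest preceding C-alpha-bearing
#' residue. Domains smaller than `min_domain` are merged into their nearest
#' neighbour (see [enforce_min_domain()]).
#'
#' @param model A [predicted_model].
#' @param n_clusters Number of clusters (>= 1).
#' @param linkage `"ward"` (default) or `"kmeans"`.
#' @param seed Integer seed for k-means (ignored for Ward).
#' @param min_domain Smallest allowed domain size in residues (default 20).
#' @return A `domain_partition` tibble.
#' @export
split_by_coordinates <- function(model, n_clusters, linkage = c("ward", "kmeans"),
                                 seed = 1, min_domain = 20) {
  linkage <- match.arg(linkage)
  res <- residues(model)
  with_ca <- res[res$has_ca, ]
  if (n_clusters < 1 || n_clusters != round(n_clusters)) {
    mr_abort("too many clusters: n_clusters must be a positive integer")
  }
  if (nrow(with_ca) < n_clusters) mr_abort("too many clusters")
  xyz <- ca_coords(with_ca)
  labels_ca <- if (n_clusters == 1) {
    rep(1L, nrow(with_ca))
  } else if (linkage == "ward") {
    cutree(hclust(dist(xyz), method = "ward.D2"), k = n_clusters)
  } else {
    withr::with_seed(seed,
      kmeans(xyz, centers = n_clusters, nstart = 10, iter.max = 100)$cluster)
  }
  domain <- rep(NA_integer_, nrow(res))
  domain[res$has_ca] <- as.integer(labels_ca)
  # residues without CA inherit from the nearest preceding CA-bearing residue
  if (anyNA(domain)) {
    filled <- domain
    for (i in seq_along(filled)) {
      if (is.na(filled[i])) {
        prev <- if (i > 1) filled[i - 1] else NA_integer_
        filled[i] <- if (!is.na(prev)) prev else NA_integer_
      }
    }
    # leading residues without CA take the first assigned label
    first_lab <- filled[which(!is.na(filled))[1]]
    filled[is.na(filled)] <- first_lab
    domain <- filled
  }
  params <- list(n_clusters = n_clusters, linkage = linkage, seed = seed,
                 min_domain = min_domain)
  part <- new_domain_partition(res, domain, method = "coords", params = params)
  enforce_min_domain(part, model, min_domain = min_domain)
}

#' Split a model into domains by parsing the PAE matrix
#'
#' Builds an undirected weighted residue graph from the predicted aligned
#' error matrix: the matrix is symmetrized as `s_ij = (pae_ij + pae_ji) / 2`,
#' an edge joins residues with `s_ij <= edge_cutoff`, and edge weights are
#' `(1 / max(s_ij, pae_floor))^pae_power` so that confidently co-placed pairs
#' bind strongly. Each connected component is then partitioned by
#' deterministic greedy modularity maximization (communities agglomerated in
#' residue order, ties to the lower index) at the given resolution.
#'
#' @param model A [predicted_model] the matrix belongs to.
#' @param pae A [pae_matrix] whose size equals the model's residue count.
#' @param pae_power Exponent on the inverse error weight (default 1).
#' @param pae_floor Smallest error in Angstroms used in the weight (default
#'   0.25), bounding the weight of near-zero PAE pairs.
#' @param edge_cutoff Largest symmetrized error in Angstroms that still forms
#'   an edge (default 10).
#' @param resolution Modularity resolution; larger values favour more, smaller
#'   domains (default 1).
#' @param min_domain Smallest allowed domain size in residues (default 20).
#' @return A `domain_partition` tibble.
#' @export
split_by_pae <- function(model, pae, pae_power = 1, pae_floor = 0.25,
                         edge_cutoff = 10, resolution = 1, min_domain = 20) {
  stopifnot(inherits(pae, "pae_matrix"))
  res <- residues(model)
  n <- nrow(res)
  if (nrow(pae) != n) mr_abort("PAE/model length mismatch")
  if (any(c(pae_power, pae_floor, edge_cutoff, resolution) <= 0)) {
    mr_abort("malformed input: PAE split parameters must be positive")
  }
  s <- (unclass(pae) + t(unclass(pae))) / 2
  w <- (1 / pmax(s, pae_floor))^pae_power
  w[s > edge_cutoff] <- 0
  diag(w) <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected", weighted = TRUE)
  comp <- igraph::components(g)$membership
  domain <- rep(NA_integer_, n)
  offset <- 0L
  for (cc in sort(unique(comp))) {
    nodes <- which(comp == cc)
    labs <- greedy_modularity(w[nodes, nodes, drop = FALSE], resolution = resolution)
    domain[nodes] <- labs + offset
    offset <- offset + max(labs)
  }
  params <- list(pae_power = pae_power, pae_floor = pae_floor,
                 edge_cutoff = edge_cutoff, resolution = resolution,
                 min_domain = min_domain)
  part <- new_domain_partition(res, domain, method = "pae", params = params)
  enforce_min_domain(part, model, min_domain = min_domain)
}

# Deterministic greedy (CNM-style) modularity agglomeration with a resolution
# parameter. Nodes start as singleton communities in index order; the merge
# with the largest modularity gain is applied (ties to the lowest community
# pair) until no merge of connected communities improves modularity.
# Returns 1-based community labels.
greedy_modularity <- function(w, resolution = 1) {
  n <- nrow(w)
  if (n == 1) return(1L)
  total <- sum(w)
  if (total == 0) return(seq_len(n))
  e <- w / total           # community-aggregated edge weight fractions
  a <- rowSums(e)          # weighted degree fractions
  members <- as.list(seq_len(n))
  repeat {
    k <- length(members)
    if (k == 1) break
    gain <- 2 * (e - resolution * outer(a, a))
    gain[e == 0] <- -Inf   # only merge connected communities
    diag(gain) <- -Inf
    best <- max(gain)
    if (best <= 1e-15) break
    hit <- which(gain == best, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    members[[i]] <- c(members[[i]], members[[j]])
    members[[j]] <- NULL
    e[i, ] <- e[i, ] + e[j, ]
    e[, i] <- e[, i] + e[, j]
    e <- e[-j, -j, drop = FALSE]
    a[i] <- a[i] + a[j]
    a <- a[-j]
  }
  labels <- integer(n)
  for (c in seq_along(members)) labels[members[[c]]] <- c
  labels
}

#' Coordinate-split sweep over one, two and three clusters
#'
#' The default preparation strategy: split the model a single way, two ways
#' and three ways, so that downstream molecular replacement can try each
#' granularity. Returns the coordinate-based partitions for k = 1, 2, 3 (in
#' that order), truncated with a warning when the model has fewer residues
#' than clusters.
#'
#' @param model A [predicted_model].
#' @param ... Passed to [split_by_coordinates()].
#' @return A list of `domain_partition` objects.
#' @export
default_split_sweep <- function(model, ...) {
  n <- sum(residues(model)$has_ca)
  ks <- seq_len(min(3L, n))
  if (length(ks) < 3) {
    warn(sprintf("model has only %d residues; sweep truncated to k = %s",
                 n, paste(ks, collapse = ",")))
  }
  map(ks, function(k) split_by_coordinates(model, n_clusters = k, ...))
}

#' Merge undersized domains into their nearest neighbour
#'
#' Every domain smaller than `min_domain` is merged into the domain whose
#' C-alpha centroid is nearest (ties to the lower domain id), smallest domain
#' first, repeating until all domains satisfy the minimum or only one domain
#' remains.
#'
#' @param partition A `domain_partition`.
#' @param model The [predicted_model] the partition belongs to.
#' @param min_domain Smallest allowed domain size in residues.
#' @return The adjusted `domain_partition`.
#' @export
enforce_min_domain <- function(partition, model, min_domain) {
  validate_partition(partition, model)
  res <- residues(model)
  domain <- partition$domain
  repeat {
    ids <- sort(unique(domain[!is.na(domain)]))
    if (length(ids) <= 1) break
    sizes <- vapply(ids, function(d) sum(domain == d, na.rm = TRUE), 1L)
    under <- ids[sizes < min_domain]
    if (length(under) == 0) break
    d0 <- under[order(sizes[match(under, ids)], under)][1]
    cent <- vapply(ids, function(d) {
      sel <- which(domain == d & res$has_ca)
      if (length(sel) == 0) return(c(NA_real_, NA_real_, NA_real_))
      c(mean(res$ca_x[sel]), mean(res$ca_y[sel]), mean(res$ca_z[sel]))
    }, numeric(3))
    others <- setdiff(ids, d0)
    dd <- vapply(others, function(d) {
      sqrt(sum((cent[, match(d, ids)] - cent[, match(d0, ids)])^2))
    }, 1)
    dd[is.na(dd)] <- Inf
    target <- others[order(dd, others)][1]
    domain[domain == d0] <- target
    domain <- renumber_domains(domain)
  }
  new_domain_partition(res, domain, method = attr(partition, "method"),
                       params = attr(partition, "params"))
}

#' Extract one search model per domain
#'
#' Carries atoms and (converted) B values over unchanged; residue identities
#' and order are preserved, so re-concatenating the outputs gives back the
#' partitioned subset of the input.
#'
#' @param model A [predicted_model].
#' @param partition A `domain_partition` for the model.
#' @return A list of [predicted_model] objects, one per domain, in domain id
#'   order.
#' @export
extract_search_models <- function(model, partition) {
  validate_partition(partition, model)
  ids <- sort(unique(partition$domain[!is.na(partition$domain)]))
  map(ids, function(d) {
    m <- subset_model(model, partition$res_index[!is.na(partition$domain) &
                                                   partition$domain == d])
    append_source_tag(m, sprintf("domain:%d/%d", d, length(ids)))
  })
}
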