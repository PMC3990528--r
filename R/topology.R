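#' @importFrom methods as is new
#' @importFrom stats runif rexp sd median quantile
#' @importFrom utils read.delim write.table packageVersion
NULL

## Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
## state afterwards. All stochastic topology code goes through this so that
## identical seeds yield identical networks regardless of ambient RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Topology configuration with exactly constant class-pair in-degrees
#'
#' Configuration shared by the fixed-in-degree random network and the
#' forwards-backwards ring lattice. Every node receives exactly
#' \code{k_from_exc} excitatory and \code{k_from_inh} inhibitory incoming
#' edges. The defaults are the full-scale study conditions: 4000 E and
#' 1000 I neurons with in-degrees 800 and 200, i.e. every class-pair
#' in-degree is 20\% of the size of the originating class.
#'
#' For inhibitory target nodes the excitatory and inhibitory in-degrees can
#' be set independently through \code{k_exc_to_inh} and \code{k_inh_to_inh};
#' by default they equal \code{k_from_exc} and \code{k_from_inh}.
#'
#' @param n_exc,n_inh Number of excitatory / inhibitory nodes. \code{n_exc}
#'   must be an integer multiple of \code{n_inh} (the lattice block
#'   construction needs an integer ratio).
#' @param k_from_exc Excitatory in-degree of every node (even, positive,
#'   \code{< n_exc}).
#' @param k_from_inh Inhibitory in-degree of every node (even, positive,
#'   \code{< n_inh}).
#' @param k_exc_to_inh,k_inh_to_inh Optional distinct in-degrees for
#'   inhibitory target nodes.
#' @param seed Integer RNG seed used by stochastic constructors.
#' @return A list of class \code{topology_config}.
#' @examples
#' topology_config(n_exc = 40, n_inh = 10, k_from_exc = 8, k_from_inh = 2)
#' @export
topology_config <- function(n_exc = 4000, n_inh = 1000,
                            k_from_exc = 800, k_from_inh = 200,
                            k_exc_to_inh = k_from_exc,
                            k_inh_to_inh = k_from_inh,
                            seed = 1L) {
  for (k in c(k_from_exc, k_from_inh, k_exc_to_inh, k_inh_to_inh))
    if (k <= 0 || k %% 2 != 0)
      stop("in-degrees must be even and positive")
  if (k_from_exc >= n_exc || k_exc_to_inh >= n_exc)
    stop("excitatory in-degree must be smaller than the number of E nodes")
  if (k_from_inh >= n_inh || k_inh_to_inh >= n_inh)
    stop("inhibitory in-degree must be smaller than the number of I nodes")
  if (n_exc %% n_inh != 0)
    stop("n_exc must be an integer multiple of n_inh")
  structure(list(n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
                 k_from_exc = as.integer(k_from_exc),
                 k_from_inh = as.integer(k_from_inh),
                 k_exc_to_inh = as.integer(k_exc_to_inh),
                 k_inh_to_inh = as.integer(k_inh_to_inh),
                 seed = as.integer(seed)),
            class = "topology_config")
}

#' Rewiring configuration for structurally-defined neuron classes
#'
#' Each node of the ring lattice independently becomes a Class 2 node with
#' probability \code{p2} (all incoming inhibitory edges get new, non-lattice
#' inhibitory origins); each remaining node becomes a Class 3 node with
#' probability \code{p3} (all incoming edges get new origins within the
#' origin's E/I class). Unselected nodes are Class 1. In-degrees per class
#' are identical before and after rewiring.
#'
#' @param p2 Probability of becoming a Class 2 node. Default 0.075, the
#'   operating point at which about 7.5\% of the network forms the small
#'   subpopulation of rewired-inhibition cells.
#' @param p3 Probability that a non-Class-2 node becomes Class 3.
#' @param exclude_original_class3 If \code{TRUE} (default) Class 3
#'   resampling also excludes each edge's original lattice origin, in
#'   symmetry with the Class 2 rule.
#' @param seed Integer RNG seed.
#' @return A list of class \code{rewire_config}.
#' @export
rewire_config <- function(p2 = 0.075, p3 = 0.05,
                          exclude_original_class3 = TRUE, seed = 1L) {
  stopifnot(p2 >= 0, p2 <= 1, p3 >= 0, p3 <= 1)
  structure(list(p2 = p2, p3 = p3,
                 exclude_original_class3 = isTRUE(exclude_original_class3),
                 seed = as.integer(seed)),
            class = "rewire_config")
}

#' Embedded modular network configuration
#'
#' Excitatory nodes are partitioned into equal, non-overlapping modules.
#' Within-module E-to-E edges exist independently with probability
#' \code{p_in}, between-module edges with probability \code{p_out}, and any
#' edge involving an inhibitory node with probability \code{p_inh}. Exactly
#' two of \code{p_in}, \code{p_out}, \code{ratio_ee} (= p_in/p_out) and
#' \code{mean_p_ee} (overall E-to-E density) must be given; the others are
#' derived.
#'
#' @param n_exc,n_inh Node counts; \code{module_size} must divide
#'   \code{n_exc}.
#' @param module_size Excitatory neurons per module.
#' @param p_in,p_out,ratio_ee,mean_p_ee E-to-E connectivity; give two.
#' @param p_inh Probability of any edge involving an I node.
#' @param seed Integer RNG seed.
#' @return A list of class \code{modular_config}.
#' @export
modular_config <- function(n_exc = 4000, n_inh = 1000, module_size = 100,
                           p_in = NULL, p_out = NULL,
                           ratio_ee = 2.5, mean_p_ee = 0.2,
                           p_inh = 0.2, seed = 1L) {
  if (n_exc %% module_size != 0)
    stop("module_size must divide n_exc")
  n_exc <- as.integer(n_exc); n_inh <- as.integer(n_inh)
  ## fraction of ordered E pairs that are within-module
  f_in <- (module_size - 1) / (n_exc - 1)
  if (!is.null(p_in) && !is.null(p_out)) {
    ratio_ee <- p_in / p_out
    mean_p_ee <- f_in * p_in + (1 - f_in) * p_out
  } else {
    if (is.null(ratio_ee) || is.null(mean_p_ee))
      stop("give two of p_in, p_out, ratio_ee, mean_p_ee")
    p_out <- mean_p_ee / (f_in * ratio_ee + 1 - f_in)
    p_in <- ratio_ee * p_out
  }
  if (p_in < p_out) stop("p_in must be at least p_out")
  for (p in c(p_in, p_out, p_inh))
    if (p < 0 || p > 1)
      stop("derived or given connection probability outside [0, 1]")
  structure(list(n_exc = n_exc, n_inh = n_inh,
                 module_size = as.integer(module_size),
                 p_in = p_in, p_out = p_out,
                 ratio_ee = ratio_ee, mean_p_ee = mean_p_ee,
                 p_inh = p_inh, seed = as.integer(seed)),
            class = "modular_config")
}

## Assemble a directed_network object from per-target origin index lists.
## `origins` is a list over targets (global 1-based ids) of global origin
## ids. Orientation everywhere: row = origin, column = target.
new_directed_network <- function(origins, n_exc, n_inh, struct_class,
                                 provenance) {
  n <- n_exc + n_inh
  lens <- lengths(origins)
  adj <- Matrix::sparseMatrix(i = unlist(origins, use.names = FALSE),
                              j = rep.int(seq_len(n), lens),
                              dims = c(n, n))
  structure(list(adj = adj,
                 ei = rep(c("E", "I"), c(n_exc, n_inh)),
                 struct_class = as.integer(struct_class),
                 n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
                 provenance = provenance),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat("Directed E/I network:", x$n_exc, "E +", x$n_inh, "I nodes,",
      length(x$adj@i), "edges\n")
  cat("  topology:", x$provenance$topology,
      if (isTRUE(x$provenance$constant_indegree))
        "(exactly constant class-pair in-degrees)"
      else "(Bernoulli edges; in-degrees not constant)", "\n")
  cat("  structural classes:",
      paste(sprintf("%d:%d", 1:3, tabulate(x$struct_class, 3)),
            collapse = " "), "\n")
  invisible(x)
}

## Per-target lists of incoming origin ids, from the column-compressed slots.
incoming_origins <- function(adj) {
  n <- ncol(adj)
  split(adj@i + 1L, factor(rep.int(seq_len(n), diff(adj@p)), levels = seq_len(n)))
}

## In-degree of every node from E origins and from I origins.
indegree_by_origin <- function(net) {
  list(from_exc = Matrix::colSums(net$adj[seq_len(net$n_exc), , drop = FALSE]),
       from_inh = Matrix::colSums(net$adj[net$n_exc + seq_len(net$n_inh), ,
                                          drop = FALSE]))
}

#' Validate the invariants of a directed E/I network
#'
#' Checks for self-edges, label consistency, and (for constructions that
#' guarantee it) exactly constant excitatory and inhibitory in-degrees for
#' every node.
#'
#' @param net A \code{directed_network}.
#' @return \code{net}, invisibly; stops on violation.
#' @export
validate_network <- function(net) {
  stopifnot(is(net$adj, "sparseMatrix"),
            nrow(net$adj) == ncol(net$adj),
            nrow(net$adj) == net$n_exc + net$n_inh,
            length(net$ei) == nrow(net$adj),
            all(net$ei %in% c("E", "I")),
            all(net$struct_class %in% 1:3))
  if (any(Matrix::diag(net$adj) != 0)) stop("self-edges are not allowed")
  if (isTRUE(net$provenance$constant_indegree)) {
    deg <- indegree_by_origin(net)
    p <- net$provenance
    e_idx <- seq_len(net$n_exc)
    i_idx <- net$n_exc + seq_len(net$n_inh)
    if (!all(deg$from_exc[e_idx] == p$k_from_exc) ||
        !all(deg$from_exc[i_idx] == p$k_exc_to_inh))
      stop("excitatory in-degree is not constant")
    if (!all(deg$from_inh[e_idx] == p$k_from_inh) ||
        !all(deg$from_inh[i_idx] == p$k_inh_to_inh))
      stop("inhibitory in-degree is not constant")
  }
  invisible(net)
}

#' Random network with exactly constant in-degrees
#'
#' The null-hypothesis topology: for every node, origins of its incoming
#' excitatory edges are drawn uniformly without replacement from the E
#' population (excluding the node itself), and likewise for inhibitory
#' origins, so every node has exactly the configured excitatory and
#' inhibitory in-degrees. All nodes are structural Class 1.
#'
#' @param config A \code{\link{topology_config}}.
#' @return A \code{directed_network}.
#' @examples
#' net <- build_random_fixed_indegree(
#'   topology_config(n_exc = 40, n_inh = 10, k_from_exc = 8, k_from_inh = 2))
#' @export
build_random_fixed_indegree <- function(config) {
  stopifnot(inherits(config, "topology_config"))
  n_e <- config$n_exc; n_i <- config$n_inh
  n <- n_e + n_i
  with_seed(config$seed, {
    origins <- vector("list", n)
    for (t in seq_len(n)) {
      e_pool <- if (t <= n_e) seq_len(n_e)[-t] else seq_len(n_e)
      i_pool <- if (t > n_e) setdiff(n_e + seq_len(n_i), t)
                else n_e + seq_len(n_i)
      k_e <- if (t <= n_e) config$k_from_exc else config$k_exc_to_inh
      k_i <- if (t <= n_e) config$k_from_inh else config$k_inh_to_inh
      origins[[t]] <- c(e_pool[sample.int(length(e_pool), k_e)],
                        i_pool[sample.int(length(i_pool), k_i)])
    }
    new_directed_network(origins, n_e, n_i, rep(1L, n),
                         provenance = c(list(topology = "random",
                                             constant_indegree = TRUE),
                                        unclass(config)))
  })
}

## 0-based symmetric lattice window {centre +/- j mod n : j = 1..k/2},
## returned 1-based.
lattice_window <- function(centre0, half, n) {
  j <- c(-(half:1), 1:half)
  ((centre0 + j) %% n) + 1L
}

#' Deterministic forwards-backwards ring lattice
#'
#' A highly clustered, deterministic topology with the same constant
#' in-degrees as the random network. E nodes form a ring in which node m
#' receives edges from its k/2 nearest neighbours in both directions; I
#' nodes form the analogous smaller ring. Cross-class edges mirror the ring
#' structure: each contiguous block of \code{c = n_exc/n_inh} E nodes
#' receives input from the same symmetric window of I nodes, and I node n
#' receives input from a symmetric window of E nodes centred at \code{c*n},
#' so that E nodes with adjacent indices connect to I nodes with adjacent
#' indices. All structural classes are 1.
#'
#' @param config A \code{\link{topology_config}} (deterministic; the seed is
#'   unused).
#' @return A \code{directed_network}. The E-to-E submatrix is symmetric, so
#'   every E-E edge is reciprocated.
#' @examples
#' lat <- build_ring_lattice(
#'   topology_config(n_exc = 16, n_inh = 4, k_from_exc = 4, k_from_inh = 2))
#' @export
build_ring_lattice <- function(config) {
  stopifnot(inherits(config, "topology_config"))
  n_e <- config$n_exc; n_i <- config$n_inh
  cc <- n_e %/% n_i
  n <- n_e + n_i
  origins <- vector("list", n)
  for (m0 in 0:(n_e - 1L)) {                     # E targets
    ee <- lattice_window(m0, config$k_from_exc %/% 2L, n_e)
    ie <- n_e + lattice_window(m0 %/% cc, config$k_from_inh %/% 2L, n_i)
    origins[[m0 + 1L]] <- c(ee, ie)
  }
  for (n0 in 0:(n_i - 1L)) {                     # I targets
    ei <- lattice_window(cc * n0, config$k_exc_to_inh %/% 2L, n_e)
    ii <- n_e + lattice_window(n0, config$k_inh_to_inh %/% 2L, n_i)
    origins[[n_e + n0 + 1L]] <- c(ei, ii)
  }
  new_directed_network(origins, n_e, n_i, rep(1L, n),
                       provenance = c(list(topology = "lattice",
                                           constant_indegree = TRUE),
                                      unclass(config)))
}

#' Rewire a ring lattice into structurally-defined neuron classes
#'
#' Nodes are independently selected as Class 2 with probability \code{p2};
#' remaining nodes as Class 3 with probability \code{p3}. For a Class 2 node
#' every incoming inhibitory edge receives a new origin sampled uniformly,
#' without duplication, from inhibitory nodes that did not project to it in
#' the lattice; its incoming excitatory edges are untouched. For a Class 3
#' node every incoming edge's origin is resampled uniformly within the
#' origin's E/I class (excluding self, duplicates and, by default, the
#' original lattice origins). Only edge origins change, so every node's
#' excitatory and inhibitory in-degrees are bit-identical before and after
#' rewiring.
#'
#' @param lattice A ring-lattice \code{directed_network} (all Class 1).
#' @param rc A \code{\link{rewire_config}}.
#' @return A \code{directed_network} with \code{struct_class} labels
#'   recording the selected classes.
#' @examples
#' lat <- build_ring_lattice(
#'   topology_config(n_exc = 40, n_inh = 10, k_from_exc = 8, k_from_inh = 2))
#' rw <- rewire_lattice(lat, rewire_config(p2 = 0.2, p3 = 0.1, seed = 7))
#' @export
rewire_lattice <- function(lattice, rc) {
  stopifnot(inherits(lattice, "directed_network"), inherits(rc, "rewire_config"))
  if (!identical(lattice$provenance$topology, "lattice"))
    stop("rewire_lattice expects a ring-lattice network")
  if (any(lattice$struct_class != 1L))
    stop("rewire_lattice expects an unrewired (all Class 1) lattice")
  n_e <- lattice$n_exc; n_i <- lattice$n_inh
  n <- n_e + n_i
  orig <- incoming_origins(lattice$adj)

  with_seed(rc$seed, {
    cls <- rep(1L, n)
    cls[runif(n) < rc$p2] <- 2L
    sel3 <- cls == 1L & runif(n) < rc$p3
    cls[sel3] <- 3L

    resample <- function(pool, exclude, k) {
      pool <- setdiff(pool, exclude)
      if (length(pool) < k)
        stop("eligible origin pool smaller than required in-degree")
      pool[sample.int(length(pool), k)]
    }

    origins <- orig
    i_all <- n_e + seq_len(n_i)
    e_all <- seq_len(n_e)
    for (t in which(cls == 2L)) {
      old <- orig[[t]]
      old_i <- old[old > n_e]
      new_i <- resample(i_all, c(old_i, t), length(old_i))
      origins[[t]] <- c(old[old <= n_e], new_i)
    }
    for (t in which(cls == 3L)) {
      old <- orig[[t]]
      old_e <- old[old <= n_e]; old_i <- old[old > n_e]
      excl_e <- if (rc$exclude_original_class3) c(old_e, t) else t
      excl_i <- if (rc$exclude_original_class3) c(old_i, t) else t
      origins[[t]] <- c(resample(e_all, excl_e, length(old_e)),
                        resample(i_all, excl_i, length(old_i)))
    }
    prov <- lattice$provenance
    prov$topology <- "rewired_lattice"
    prov$p2 <- rc$p2; prov$p3 <- rc$p3
    prov$exclude_original_class3 <- rc$exclude_original_class3
    prov$rewire_seed <- rc$seed
    new_directed_network(origins, n_e, n_i, cls, prov)
  })
}

#' Embedded modular excitatory network
#'
#' Every excitatory node belongs to exactly one module of
#' \code{module_size} nodes. Within-module E-to-E edges exist independently
#' with probability \code{p_in}, between-module edges with \code{p_out}, and
#' every edge class involving an inhibitory node with \code{p_inh}. Unlike
#' the other constructors this topology is Bernoulli: in-degrees are not
#' constant, which is flagged in the network's provenance.
#'
#' @param mc A \code{\link{modular_config}}.
#' @return A \code{directed_network}; \code{struct_class} is all 1, and the
#'   module assignment is stored in \code{provenance$module}.
#' @export
build_embedded_modular <- function(mc) {
  stopifnot(inherits(mc, "modular_config"))
  n_e <- mc$n_exc; n_i <- mc$n_inh
  n <- n_e + n_i
  module <- rep(seq_len(n_e %/% mc$module_size), each = mc$module_size)
  with_seed(mc$seed, {
    origins <- vector("list", n)
    for (t in seq_len(n_e)) {
      p_vec <- ifelse(module == module[t], mc$p_in, mc$p_out)
      e_or <- which(runif(n_e) < p_vec)
      e_or <- e_or[e_or != t]
      i_or <- n_e + which(runif(n_i) < mc$p_inh)
      origins[[t]] <- c(e_or, i_or)
    }
    for (t in n_e + seq_len(n_i)) {
      e_or <- which(runif(n_e) < mc$p_inh)
      i_or <- n_e + which(runif(n_i) < mc$p_inh)
      i_or <- i_or[i_or != t]
      origins[[t]] <- c(e_or, i_or)
    }
    new_directed_network(origins, n_e, n_i, rep(1L, n),
                         provenance = c(list(topology = "embedded_modular",
                                             constant_indegree = FALSE,
                                             module = module),
                                        unclass(mc)))
  })
}

#' Class-pair in/out-degree profile
#'
#' Summaries (min, mean, max) of in- and out-degrees for every ordered pair
#' of node classes, at two granularities: the physiological E/I classes and
#' the six structural classes (E1..I3, omitting empty ones). For the
#' in-degree rows the target class is the summarised population; for the
#' out-degree columns the origin class is.
#'
#' @param net A \code{directed_network}.
#' @return A data frame with columns \code{grouping} (\code{"ei"} or
#'   \code{"structural"}), \code{origin}, \code{target}, \code{in_min},
#'   \code{in_mean}, \code{in_max}, \code{out_min}, \code{out_mean},
#'   \code{out_max}.
#' @export
in_degree_profile <- function(net) {
  six <- paste0(net$ei, net$struct_class)
  groupings <- list(ei = net$ei, structural = six)
  adj <- net$adj
  res <- list()
  for (gname in names(groupings)) {
    g <- groupings[[gname]]
    labs <- sort(unique(g))
    for (og in labs) {
      o_idx <- which(g == og)
      in_deg <- Matrix::colSums(adj[o_idx, , drop = FALSE])
      for (tg in labs) {
        t_idx <- which(g == tg)
        ind <- in_deg[t_idx]
        outd <- Matrix::rowSums(adj[, t_idx, drop = FALSE])[o_idx]
        res[[length(res) + 1L]] <- data.frame(
          grouping = gname, origin = og, target = tg,
          in_min = min(ind), in_mean = mean(ind), in_max = max(ind),
          out_min = min(outd), out_mean = mean(outd), out_max = max(outd))
      }
    }
  }
  do.call(rbind, res)
}
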