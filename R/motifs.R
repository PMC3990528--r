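## numeric (0/1) copy of the pattern adjacency, for matrix products
num_adj <- function(net) {
  A <- as(net$adj, "dMatrix")
  A@x[] <- 1
  A
}

#' Per-node signed reciprocal-connection counts
#'
#' For every node, the number of partners connected in both directions,
#' computed from the elementwise product of the adjacency matrix with its
#' transpose. Counts are split by feedback sign: a feedback path is positive
#' when it contains an even number of inhibitory edges, so E-E and I-I
#' reciprocal pairs are positive feedback and E-I pairs negative feedback.
#'
#' @param net A \code{directed_network}.
#' @return A data frame with columns \code{node}, \code{ei},
#'   \code{struct_class}, \code{reciprocal_total},
#'   \code{reciprocal_positive}, \code{reciprocal_negative}.
#' @examples
#' net <- generate_fixture_network("toy_recip")
#' reciprocal_counts(net)
#' @export
reciprocal_counts <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  A <- num_adj(net)
  R <- A * Matrix::t(A)                 # symmetric 0/1: reciprocated pairs
  same <- as.numeric(net$ei == "E")
  with_e <- as.vector(R %*% same)       # reciprocal partners that are E
  with_i <- as.vector(R %*% (1 - same))
  pos <- ifelse(net$ei == "E", with_e, with_i)
  neg <- ifelse(net$ei == "E", with_i, with_e)
  data.frame(node = seq_len(nrow(A)), ei = net$ei,
             struct_class = net$struct_class,
             reciprocal_total = as.integer(pos + neg),
             reciprocal_positive = as.integer(pos),
             reciprocal_negative = as.integer(neg))
}

#' Per-node feed-forward inhibition (FFI) motif counts
#'
#' For each reference node x, the number of (E, I) pairs with edges E->x,
#' I->x and E->I: a single excitatory source both excites the reference
#' node and disynaptically inhibits it. Computed as the diagonal of the
#' product of three class-restricted submatrices of the adjacency.
#'
#' @param net A \code{directed_network}.
#' @return Integer vector of counts, one per node (the convergence target).
#' @examples
#' ffi_counts(generate_fixture_network("toy_ffi"))
#' @export
ffi_counts <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  A <- num_adj(net)
  e <- seq_len(net$n_exc); i <- net$n_exc + seq_len(net$n_inh)
  ## diag( t(A[E,]) %*% A[E,I] %*% A[I,] )
  P <- Matrix::t(A[e, , drop = FALSE]) %*% A[e, i, drop = FALSE]
  as.integer(round(Matrix::rowSums(P * Matrix::t(A[i, , drop = FALSE]))))
}

#' Per-node directed 3-cycle motif counts
#'
#' For each reference node x, the number of directed three-edge cycles
#' through x of the requested family: \code{"eei"} counts x->E->I->x
#' (negative feedback: one inhibitory edge) and \code{"eee"} counts
#' x->E->E->x (all-excitation positive feedback). Each node on a cycle
#' counts the cycle once as reference, via the transposed-product variant of
#' the convergent-motif diagonal.
#'
#' @param net A \code{directed_network}.
#' @param family \code{"eei"} or \code{"eee"}.
#' @return Integer vector of counts, one per node.
#' @export
cycle_counts <- function(net, family = c("eei", "eee")) {
  family <- match.arg(family)
  stopifnot(inherits(net, "directed_network"))
  A <- num_adj(net)
  e <- seq_len(net$n_exc); i <- net$n_exc + seq_len(net$n_inh)
  mid <- if (family == "eei") i else e
  ## diag( A[,E] %*% A[E,mid] %*% A[mid,] )
  P <- A[, e, drop = FALSE] %*% A[e, mid, drop = FALSE]
  as.integer(round(Matrix::rowSums(P * Matrix::t(A[mid, , drop = FALSE]))))
}

#' Motif pattern specification
#'
#' Describes a 2- or 3-node motif for the brute-force enumerator: a list of
#' directed edges over the roles \code{x} (reference), \code{a}, \code{b},
#' with an E/I constraint per non-reference role. The feedback sign is the
#' parity of inhibitory edges in the pattern.
#'
#' @param edges Two-column character matrix (from-role, to-role).
#' @param roles Named character vector mapping non-reference roles to
#'   \code{"E"}, \code{"I"} or \code{"any"}.
#' @param name Optional label.
#' @return A list of class \code{motif_spec}.
#' @export
motif_spec <- function(edges, roles = c(a = "any", b = "any"), name = "") {
  edges <- matrix(as.character(edges), ncol = 2)
  all_roles <- unique(as.vector(edges))
  stopifnot("x" %in% all_roles, all(all_roles %in% c("x", "a", "b")))
  structure(list(edges = edges, roles = roles, name = name),
            class = "motif_spec")
}

## built-in specs matching the fast counters
builtin_motif_spec <- function(family) {
  switch(family,
    ffi = motif_spec(rbind(c("a", "x"), c("b", "x"), c("a", "b")),
                     roles = c(a = "E", b = "I"), name = "ffi"),
    eei = motif_spec(rbind(c("x", "a"), c("a", "b"), c("b", "x")),
                     roles = c(a = "E", b = "I"), name = "eei"),
    eee = motif_spec(rbind(c("x", "a"), c("a", "b"), c("b", "x")),
                     roles = c(a = "E", b = "E"), name = "eee"),
    stop("unknown motif family: ", family))
}

#' Brute-force motif enumeration oracle
#'
#' Exhaustively enumerates ordered node tuples matching a
#' \code{\link{motif_spec}} and attributes each instance to the reference
#' node, exactly as the matrix-product counters do. All motif nodes must be
#' distinct. Intended for small networks (hundreds of nodes) as an
#' independent check of \code{\link{ffi_counts}}, \code{\link{cycle_counts}}
#' and \code{\link{reciprocal_counts}}.
#'
#' @param net A \code{directed_network}.
#' @param spec A \code{\link{motif_spec}}, or a family name
#'   (\code{"ffi"}, \code{"eei"}, \code{"eee"}).
#' @return Integer vector of per-node reference counts.
#' @export
brute_force_motif_counts <- function(net, spec) {
  stopifnot(inherits(net, "directed_network"))
  if (is.character(spec)) spec <- builtin_motif_spec(spec)
  A <- as.matrix(net$adj)
  n <- nrow(A)
  roles <- setdiff(unique(as.vector(spec$edges)), "x")
  ok_class <- function(role, node) {
    want <- spec$roles[[role]]
    is.null(want) || want == "any" || net$ei[node] == want
  }
  counts <- integer(n)
  cand <- lapply(roles, function(r)
    which(vapply(seq_len(n), function(v) ok_class(r, v), logical(1))))
  names(cand) <- roles
  for (x in seq_len(n)) {
    if (length(roles) == 1) {
      for (a in cand[[1]]) {
        if (a == x) next
        assign_ <- c(x = x, stats::setNames(a, roles[1]))
        if (all(A[cbind(assign_[spec$edges[, 1]],
                        assign_[spec$edges[, 2]])] != 0))
          counts[x] <- counts[x] + 1L
      }
    } else {
      for (a in cand[[1]]) {
        if (a == x) next
        for (b in cand[[2]]) {
          if (b == x || b == a) next
          assign_ <- c(x = x, stats::setNames(c(a, b), roles))
          if (all(A[cbind(assign_[spec$edges[, 1]],
                          assign_[spec$edges[, 2]])] != 0))
            counts[x] <- counts[x] + 1L
        }
      }
    }
  }
  counts
}

#' Identify structural neuron classes from connectivity alone
#'
#' Within each physiological population (E, I), nodes are stratified by
#' their total reciprocal-connection count: the integer histogram of counts
#' separates into clearly divided groups for lattice-derived networks, and
#' strata are split at the widest runs of empty integer bins (at most two
#' separators, hence at most three strata). Strata are mapped to classes by
#' descending reciprocal count — unrewired Class 1 nodes retain the most
#' reciprocated lattice edges, Class 2 fewer, Class 3 fewest.
#'
#' @param net A \code{directed_network}.
#' @param max_classes Maximum number of strata per population.
#' @return A list of class \code{class_identification}: \code{class}
#'   (integer per node), \code{n_strata} per population, and
#'   \code{warning_flag} (\code{TRUE} when a population separated into
#'   fewer than \code{max_classes} strata).
#' @examples
#' lat <- build_ring_lattice(
#'   topology_config(n_exc = 40, n_inh = 10, k_from_exc = 8, k_from_inh = 2))
#' identify_structural_classes(lat)$class  # all 1
#' @export
identify_structural_classes <- function(net, max_classes = 3L) {
  stopifnot(inherits(net, "directed_network"))
  rc <- reciprocal_counts(net)
  cls <- integer(nrow(rc))
  n_strata <- c(E = NA_integer_, I = NA_integer_)
  for (pop in c("E", "I")) {
    idx <- which(rc$ei == pop)
    counts <- rc$reciprocal_total[idx]
    occupied <- sort(unique(counts))
    ## gaps between consecutive occupied integer values, widest first
    gaps <- diff(occupied) - 1L
    sep <- order(gaps, decreasing = TRUE)
    sep <- sep[gaps[sep] >= 1L]
    sep <- sort(sep[seq_len(min(length(sep), max_classes - 1L))])
    ## stratum id per occupied value (1 = lowest counts)
    stratum_of_value <- findInterval(occupied, occupied[c(1L, sep + 1L)])
    stratum <- stratum_of_value[match(counts, occupied)]
    k <- max(stratum)
    n_strata[pop] <- k
    ## descending mean count -> class 1, 2, 3
    cls[idx] <- (k + 1L) - stratum
  }
  structure(list(class = cls, n_strata = n_strata,
                 warning_flag = any(n_strata < max_classes)),
            class = "class_identification")
}
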