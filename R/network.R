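#' Topology specification for the three-column network
#'
#' The standard network has three cortical columns (A = recorded,
#' B = stimulated, C = control), each with 40 excitatory and 40 inhibitory
#' units, plus a 40-motoneuron pool per column. Excitatory units connect
#' sparsely to all other cortical units in any column; inhibitory units
#' connect within their own column only. Each column's motoneurons receive
#' corticomotoneuronal input from that column's excitatory units.
#'
#' @param n_excitatory,n_inhibitory Cortical units per column.
#' @param n_motoneurons Motoneurons per pool.
#' @param p_exc Probability of each excitatory cortical connection.
#' @param p_inh Probability of each within-column inhibitory connection.
#' @param p_cm Probability of each corticomotoneuronal connection.
#' @param init_strength_frac Range of initial connection strengths as a
#'   fraction of the maximum strength.
#' @param cm_strength Strength of (non-plastic) corticomotoneuronal
#'   connections (uV).
#' @param moto_threshold Range of motoneuron thresholds (mV), assigned in
#'   increasing order across the pool.
#' @param muap_amplitude Range of motor unit potential amplitudes (mV),
#'   co-sorted with the thresholds (size principle).
#' @return An object of class `topology_spec`.
#' @export
topology_spec <- function(n_excitatory = 40, n_inhibitory = 40,
                          n_motoneurons = 40,
                          p_exc = 1 / 6, p_inh = 1 / 3, p_cm = 1 / 3,
                          init_strength_frac = c(0.2, 0.6),
                          cm_strength = 350,
                          moto_threshold = c(5, 6),
                          muap_amplitude = c(0.5, 1.5)) {
  stopifnot(n_excitatory >= 1, n_inhibitory >= 0, n_motoneurons >= 0,
            p_exc >= 0, p_exc <= 1, p_inh >= 0, p_inh <= 1,
            p_cm >= 0, p_cm <= 1,
            length(init_strength_frac) == 2,
            all(init_strength_frac > 0), all(init_strength_frac <= 1),
            cm_strength > 0)
  structure(list(n_excitatory = n_excitatory, n_inhibitory = n_inhibitory,
                 n_motoneurons = n_motoneurons, p_exc = p_exc,
                 p_inh = p_inh, p_cm = p_cm,
                 init_strength_frac = init_strength_frac,
                 cm_strength = cm_strength,
                 moto_threshold = moto_threshold,
                 muap_amplitude = muap_amplitude),
            class = "topology_spec")
}

COLUMNS <- c("A", "B", "C")

column_index <- function(col) {
  if (is.character(col)) col <- match(toupper(col), COLUMNS)
  if (any(is.na(col)) || any(!col %in% 1:3)) stop("unknown column")
  col
}

#' Build a randomized three-column spiking network
#'
#' Draws every potential connection independently: excitatory cortical
#' source to any other cortical unit with `p_exc`; inhibitory source to any
#' other unit of the same column with `p_inh`; column excitatory units to
#' their motor pool with `p_cm`. Self-connections are never created.
#' Cortical weights start at uniform strengths in
#' `init_strength_frac * max_strength`, signed by the source type, and are
#' plastic; corticomotoneuronal weights are fixed. The build is a pure
#' function of `(spec, seed)`.
#'
#' @param spec A [topology_spec()].
#' @param sim A [sim_params()].
#' @param plast A [plasticity_params()].
#' @param seed Integer seed for the topology draw.
#' @return An object of class `spiking_network`: a list with `units` and
#'   `edges` data frames plus the parameter objects.
#' @export
#' @examples
#' net <- build_network(seed = 1)
#' table(net$units$type, net$units$column)
build_network <- function(spec = topology_spec(), sim = sim_params(),
                          plast = plasticity_params(sim = sim), seed = 1) {
  set.seed(seed)
  ne <- spec$n_excitatory; ni <- spec$n_inhibitory; nm <- spec$n_motoneurons
  per_col <- ne + ni
  ncort <- 3 * per_col

  units <- data.frame(
    id = seq_len(ncort + 3 * nm),
    column = c(rep(1:3, each = per_col), rep(1:3, each = nm)),
    type = c(rep(rep(c("e", "i"), c(ne, ni)), 3), rep("m", 3 * nm)),
    stringsAsFactors = FALSE)
  units$threshold <- ifelse(
    units$type == "m",
    rep(seq(spec$moto_threshold[1], spec$moto_threshold[2],
            length.out = max(nm, 2))[seq_len(nm)], 3),
    sim$theta)
  units$muap <- ifelse(
    units$type == "m",
    rep(seq(spec$muap_amplitude[1], spec$muap_amplitude[2],
            length.out = max(nm, 2))[seq_len(nm)], 3),
    0)

  cort <- units$id[units$type != "m"]
  exc <- units$id[units$type == "e"]
  inh <- units$id[units$type == "i"]

  # excitatory -> all other cortical units, any column
  src_e <- rep(exc, each = ncort)
  dst_e <- rep(cort, times = length(exc))
  keep <- src_e != dst_e & stats::runif(length(src_e)) < spec$p_exc
  edges_e <- data.frame(src = src_e[keep], dst = dst_e[keep], sign = 1)

  # inhibitory -> all other units of the same column
  edges_i <- NULL
  if (length(inh)) {
    src_i <- dst_i <- integer(0)
    for (k in 1:3) {
      ck <- cort[units$column[cort] == k]
      ik <- intersect(inh, ck)
      s <- rep(ik, each = length(ck)); d <- rep(ck, times = length(ik))
      ok <- s != d & stats::runif(length(s)) < spec$p_inh
      src_i <- c(src_i, s[ok]); dst_i <- c(dst_i, d[ok])
    }
    edges_i <- data.frame(src = src_i, dst = dst_i, sign = -1)
  }

  edges <- rbind(edges_e, edges_i)
  lo <- spec$init_strength_frac[1] * plast$max_strength
  hi <- spec$init_strength_frac[2] * plast$max_strength
  edges$weight <- edges$sign *
    weight_from_strength(stats::runif(nrow(edges), lo, hi), plast)
  edges$plastic <- TRUE

  # corticomotoneuronal connections: parent-column excitatory -> pool
  if (nm > 0) {
    moto <- units$id[units$type == "m"]
    src_m <- dst_m <- integer(0)
    for (k in 1:3) {
      ek <- exc[units$column[exc] == k]
      mk <- moto[units$column[moto] == k]
      s <- rep(ek, each = length(mk)); d <- rep(mk, times = length(ek))
      ok <- stats::runif(length(s)) < spec$p_cm
      src_m <- c(src_m, s[ok]); dst_m <- c(dst_m, d[ok])
    }
    if (length(src_m)) {
      edges <- rbind(edges, data.frame(
        src = src_m, dst = dst_m, sign = 1,
        weight = weight_from_strength(spec$cm_strength, plast),
        plastic = FALSE))
    }
  }
  edges$sign <- NULL
  rownames(edges) <- NULL

  structure(list(units = units, edges = edges, spec = spec, sim = sim,
                 plast = plast, seed = seed,
                 correlated_bias_removed = FALSE),
            class = "spiking_network")
}

#' @export
print.spiking_network <- function(x, ...) {
  cat("spiking_network:", nrow(x$units), "units (",
      sum(x$units$type != "m"), "cortical,",
      sum(x$units$type == "m"), "motoneurons ),",
      nrow(x$edges), "connections\n")
  invisible(x)
}

#' Remove all cortical connections between two columns
#'
#' Deletes every cortical edge in both directions between the two columns,
#' leaving all other edges and their weights untouched, so a lesioned
#' network is an exact twin of its intact original apart from the removed
#' pathway. Idempotent.
#'
#' @param network A [build_network()] result.
#' @param column_x,column_y Column labels ("A", "B", "C") or indices; must
#'   differ.
#' @return The lesioned network.
#' @export
lesion_connections <- function(network, column_x, column_y) {
  cx <- column_index(column_x); cy <- column_index(column_y)
  if (cx == cy) stop("cannot lesion a column against itself")
  colu <- network$units$column
  cortical <- network$units$type != "m"
  e <- network$edges
  drop <- (colu[e$src] == cx & colu[e$dst] == cy |
           colu[e$src] == cy & colu[e$dst] == cx) &
    cortical[e$src] & cortical[e$dst]
  network$edges <- e[!drop, , drop = FALSE]
  rownames(network$edges) <- NULL
  network
}

#' Fix and fully connect intracolumn connectivity
#'
#' Replaces all within-column cortical connections by a complete set of
#' fixed (non-plastic) connections with strengths drawn uniformly from
#' `strength_range`, signed by source type. Intercolumn connections remain
#' plastic. With `remove_correlated_bias = TRUE` the compiled run drops the
#' correlated share of the external bias, so recurrent intracolumn activity
#' is the only synchrony source.
#'
#' @param network A [build_network()] result.
#' @param strength_range Fixed intracolumn strengths (uV).
#' @param remove_correlated_bias Drop correlated bias input at compile time.
#' @return The modified network.
#' @export
configure_fic <- function(network, strength_range = c(200, 300),
                          remove_correlated_bias = TRUE) {
  stopifnot(length(strength_range) == 2, all(strength_range > 0))
  u <- network$units
  colu <- u$column
  cortical <- u$type != "m"
  e <- network$edges
  intra <- colu[e$src] == colu[e$dst] & cortical[e$src] & cortical[e$dst]
  e <- e[!intra, , drop = FALSE]

  src <- dst <- integer(0); sgn <- numeric(0)
  for (k in 1:3) {
    ck <- u$id[cortical & colu == k]
    s <- rep(ck, each = length(ck)); d <- rep(ck, times = length(ck))
    ok <- s != d
    src <- c(src, s[ok]); dst <- c(dst, d[ok])
    sgn <- c(sgn, ifelse(u$type[s[ok]] == "i", -1, 1))
  }
  fic <- data.frame(
    src = src, dst = dst,
    weight = sgn * weight_from_strength(
      stats::runif(length(src), strength_range[1], strength_range[2]),
      network$plast),
    plastic = FALSE)
  network$edges <- rbind(e, fic)
  rownames(network$edges) <- NULL
  network$correlated_bias_removed <- isTRUE(remove_correlated_bias)
  network
}
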