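#' Network construction parameters
#'
#' @param n_excitatory Number of excitatory neurons (>= 0).
#' @param n_inhibitory Number of inhibitory neurons (>= 0). The conventional
#'   cortical ratio is 4:1 excitatory:inhibitory, the default here.
#' @param connection_density Probability in (0,1] that an allowed neuron pair
#'   is connected. Default 1 (every allowed pair connected, one random
#'   direction each), matching the fully connected regime in which the average
#'   degree grows with network size.
#' @param ei_fixed_weight Fixed weight of excitatory->inhibitory synapses.
#' @param ie_fixed_weight Fixed weight of inhibitory->excitatory synapses.
#' @param n_external Number of independent external Poisson sources per neuron.
#'   Each source connects with a fixed weight drawn uniform on [0,1].
#' @param seed Integer seed used by [build_network()].
#' @return An object of class `network_config`.
#' @export
network_config <- function(n_excitatory = 500, n_inhibitory = 125,
                           connection_density = 1,
                           ei_fixed_weight = 0.5, ie_fixed_weight = 0.5,
                           n_external = 2000, seed = 1L) {
  if (n_excitatory < 0 || n_inhibitory < 0)
    stop("network_config: neuron counts must be >= 0")
  if (n_excitatory + n_inhibitory < 1)
    stop("network_config: network must contain at least one neuron")
  if (connection_density <= 0 || connection_density > 1)
    stop("network_config: connection_density must lie in (0,1]")
  for (w in c(ei_fixed_weight, ie_fixed_weight))
    if (w < 0 || w > 1) stop("network_config: fixed weights must lie in [0,1]")
  if (n_external < 0) stop("network_config: n_external must be >= 0")
  structure(list(n_excitatory = as.integer(n_excitatory),
                 n_inhibitory = as.integer(n_inhibitory),
                 connection_density = connection_density,
                 ei_fixed_weight = ei_fixed_weight,
                 ie_fixed_weight = ie_fixed_weight,
                 n_external = as.integer(n_external),
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Build a Dale-constrained, unidirectional random wiring diagram
#'
#' Neurons `1..n_excitatory` are excitatory, the rest inhibitory. For each
#' unordered pair that is not inhibitory-inhibitory, with probability
#' `connection_density` exactly one directed edge is created, its direction
#' chosen uniformly; the reverse edge never coexists. Excitatory->excitatory
#' weights are drawn uniform on [0,1] and are plastic; excitatory->inhibitory
#' and inhibitory->excitatory weights are fixed. Each neuron additionally
#' receives `n_external` external sources with fixed weights uniform on [0,1]
#' (stored in the `external_weights` attribute as a list per neuron).
#'
#' @param config A [network_config()] object.
#' @return A `synapse_table`: a data.frame with columns `pre`, `post`,
#'   `weight`, `kind` (factor: `EE`, `EI`, `IE`), `plastic` (logical), plus
#'   attributes `n_neurons`, `n_excitatory`, `n_inhibitory`,
#'   `external_weights`.
#' @examples
#' net <- build_network(network_config(n_excitatory = 4, n_inhibitory = 1,
#'                                     n_external = 10))
#' nrow(net) # 10 edges at density 1
#' @export
build_network <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  set.seed(config$seed)
  nE <- config$n_excitatory
  nI <- config$n_inhibitory
  n <- nE + nI
  is_exc <- c(rep(TRUE, nE), rep(FALSE, nI))

  # allowed unordered pairs: all pairs except inhibitory-inhibitory
  pairs <- utils::combn(n, 2L)
  allowed <- !(pairs[1L, ] > nE & pairs[2L, ] > nE)
  pairs <- pairs[, allowed, drop = FALSE]
  keep <- stats::runif(ncol(pairs)) <= config$connection_density
  pairs <- pairs[, keep, drop = FALSE]
  flip <- stats::runif(ncol(pairs)) < 0.5
  pre <- ifelse(flip, pairs[2L, ], pairs[1L, ])
  post <- ifelse(flip, pairs[1L, ], pairs[2L, ])

  kind <- character(length(pre))
  kind[is_exc[pre] & is_exc[post]] <- "EE"
  kind[is_exc[pre] & !is_exc[post]] <- "EI"
  kind[!is_exc[pre] & is_exc[post]] <- "IE"
  weight <- numeric(length(pre))
  weight[kind == "EE"] <- stats::runif(sum(kind == "EE"))
  weight[kind == "EI"] <- config$ei_fixed_weight
  weight[kind == "IE"] <- config$ie_fixed_weight

  tab <- data.frame(pre = as.integer(pre), post = as.integer(post),
                    weight = weight,
                    kind = factor(kind, levels = c("EE", "EI", "IE")),
                    plastic = kind == "EE")
  attr(tab, "n_neurons") <- n
  attr(tab, "n_excitatory") <- nE
  attr(tab, "n_inhibitory") <- nI
  attr(tab, "external_weights") <-
    lapply(seq_len(n), function(i) stats::runif(config$n_external))
  class(tab) <- c("synapse_table", "data.frame")
  tab
}

#' In-degree of one neuron
#'
#' Number of internal (within-network) synapses terminating on a neuron.
#'
#' @param table A `synapse_table` from [build_network()].
#' @param neuron_id Neuron index.
#' @return Integer count.
#' @export
in_degree <- function(table, neuron_id) {
  n <- attr(table, "n_neurons")
  if (!is.numeric(neuron_id) || neuron_id < 1 || neuron_id > n)
    stop("in_degree: unknown neuron id")
  sum(table$post == neuron_id)
}

#' Average degree of the network
#'
#' Internal edge count divided by neuron count; the standard density proxy
#' for a directed network in which each connected pair carries one edge.
#'
#' @param table A `synapse_table`.
#' @return Numeric scalar.
#' @export
average_degree <- function(table) {
  n <- attr(table, "n_neurons")
  if (is.null(n) || n < 1) stop("average_degree: empty network")
  nrow(table) / n
}

#' Serialize / reload a wiring diagram
#'
#' The edge list round-trips bit-exactly through a plain CSV; external weights
#' travel in a companion CSV (`<path>.external.csv`, columns neuron, source,
#' weight).
#'
#' @param table A `synapse_table`.
#' @param path CSV path.
#' @return `write_edges`: invisibly, the path. `read_edges`: the restored
#'   `synapse_table`.
#' @export
write_edges <- function(table, path) {
  df <- as.data.frame(table)
  df$kind <- as.character(df$kind)
  df$weight <- sprintf("%.17g", df$weight)   # bit-exact round trip
  utils::write.csv(cbind(df,
                         n_neurons = attr(table, "n_neurons"),
                         n_excitatory = attr(table, "n_excitatory")),
                   path, row.names = FALSE)
  ext <- attr(table, "external_weights")
  extdf <- data.frame(
    neuron = rep(seq_along(ext), lengths(ext)),
    source = unlist(lapply(ext, seq_along), use.names = FALSE),
    weight = sprintf("%.17g", unlist(ext, use.names = FALSE)))
  utils::write.csv(extdf, paste0(path, ".external.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  df <- utils::read.csv(path)
  n <- df$n_neurons[1L]
  nE <- df$n_excitatory[1L]
  tab <- data.frame(pre = as.integer(df$pre), post = as.integer(df$post),
                    weight = df$weight,
                    kind = factor(df$kind, levels = c("EE", "EI", "IE")),
                    plastic = df$plastic)
  extdf <- utils::read.csv(paste0(path, ".external.csv"))
  ext <- lapply(seq_len(n), function(i) extdf$weight[extdf$neuron == i])
  attr(tab, "n_neurons") <- n
  attr(tab, "n_excitatory") <- nE
  attr(tab, "n_inhibitory") <- n - nE
  attr(tab, "external_weights") <- ext
  class(tab) <- c("synapse_table", "data.frame")
  tab
}

#' Build a single-neuron "network": one cell with m plastic external synapses
#'
#' The standard single-cell preparation: one excitatory LIF neuron receiving
#' `m` independent external Poisson trains through plastic synapses with
#' initial weights uniform on [0,1]. Represented as a `synapse_table` with no
#' internal edges and plastic external weights.
#'
#' @param m Number of external synapses.
#' @param seed Integer seed for the initial weights.
#' @return A `synapse_table` with attribute `external_plastic = TRUE`.
#' @export
single_neuron_table <- function(m = 2000, seed = 1L) {
  set.seed(seed)
  tab <- data.frame(pre = integer(0), post = integer(0), weight = numeric(0),
                    kind = factor(character(0), levels = c("EE", "EI", "IE")),
                    plastic = logical(0))
  attr(tab, "n_neurons") <- 1L
  attr(tab, "n_excitatory") <- 1L
  attr(tab, "n_inhibitory") <- 0L
  attr(tab, "external_weights") <- list(stats::runif(m))
  attr(tab, "external_plastic") <- TRUE
  class(tab) <- c("synapse_table", "data.frame")
  tab
}
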