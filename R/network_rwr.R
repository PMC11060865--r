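#' Construct a multiplex disease-gene-protein network
#'
#' Builds a validated multiplex network from three undirected edge layers:
#' disease--disease similarity, disease--gene association, and
#' protein--protein interaction (protein nodes are gene nodes). Duplicate
#' undirected edges within a layer are collapsed with summed weights;
#' self-loops are rejected.
#'
#' Node types come from `node_types` when supplied, otherwise they are
#' inferred: endpoints of the disease--disease layer are diseases, endpoints
#' of the protein--protein layer are genes, and in the disease--gene layer
#' the first column is read as the disease and the second as the gene.
#'
#' @param disease_disease,disease_gene,protein_protein Data frames with
#'   columns `u`, `v` and optional `weight` (default 1; weights must be
#'   non-negative). Any layer may be empty.
#' @param node_types Optional data frame `node`, `type` with `type` in
#'   `{"gene", "disease"}`.
#' @return A `multiplex_network`: list with `nodes` (data frame `id`, `type`)
#'   and `layers` (named list of edge data frames).
#' @export
multiplex_network <- function(disease_disease, disease_gene, protein_protein,
                              node_types = NULL) {
  layers <- list(disease_disease = disease_disease,
    disease_gene = disease_gene, protein_protein = protein_protein)
  layers <- lapply(names(layers), function(nm) {
    e <- as.data.frame(layers[[nm]])
    if (nrow(e) == 0L)
      return(data.frame(u = character(0), v = character(0),
        weight = numeric(0)))
    if (ncol(e) < 2L) stop("layer ", nm, " needs columns u, v[, weight]")
    out <- data.frame(u = as.character(e[[1]]), v = as.character(e[[2]]),
      weight = if (ncol(e) >= 3L) as.numeric(e[[3]]) else 1,
      stringsAsFactors = FALSE)
    if (any(is.na(out$weight)) || any(out$weight < 0))
      stop("layer ", nm, " has missing or negative edge weights")
    loops <- out$u == out$v
    if (any(loops))
      stop("self-loop in layer ", nm, ": ", out$u[which(loops)[1]])
    # canonical undirected orientation, then collapse duplicates
    swap <- out$u > out$v
    tmp <- out$u[swap]; out$u[swap] <- out$v[swap]; out$v[swap] <- tmp
    agg <- aggregate(weight ~ u + v, data = out, FUN = sum)
    agg[order(agg$u, agg$v), , drop = FALSE]
  })
  names(layers) <- c("disease_disease", "disease_gene", "protein_protein")

  type_of <- new.env(parent = emptyenv())
  assign_type <- function(node, type, where) {
    known <- type_of[[node]]
    if (is.null(known)) {
      type_of[[node]] <- type
    } else if (!identical(known, type)) {
      stop("type-inconsistent node '", node, "' in ", where,
        ": declared ", known, ", implied ", type)
    }
  }
  if (!is.null(node_types)) {
    node_types <- as.data.frame(node_types)
    stopifnot(all(c("node", "type") %in% names(node_types)))
    if (!all(node_types$type %in% c("gene", "disease")))
      stop("node types must be 'gene' or 'disease'")
    for (i in seq_len(nrow(node_types)))
      assign_type(as.character(node_types$node[i]),
        as.character(node_types$type[i]), "node_types")
  }
  for (n in unique(c(layers$disease_disease$u, layers$disease_disease$v)))
    assign_type(n, "disease", "disease_disease layer")
  for (n in unique(c(layers$protein_protein$u, layers$protein_protein$v)))
    assign_type(n, "gene", "protein_protein layer")
  # infer remaining disease_gene endpoint types from the ORIGINAL orientation
  # (convention: first column disease, second column gene), then validate
  odg <- as.data.frame(disease_gene)
  for (i in seq_len(nrow(odg))) {
    u <- as.character(odg[[1]][i])
    v <- as.character(odg[[2]][i])
    tu <- type_of[[u]]
    tv <- type_of[[v]]
    if (is.null(tu) && is.null(tv)) {
      assign_type(u, "disease", "disease_gene layer")
      assign_type(v, "gene", "disease_gene layer")
    } else if (is.null(tu)) {
      assign_type(u, setdiff(c("disease", "gene"), tv), "disease_gene layer")
    } else if (is.null(tv)) {
      assign_type(v, setdiff(c("disease", "gene"), tu), "disease_gene layer")
    }
    if (identical(type_of[[u]], type_of[[v]]))
      stop("type-inconsistent edge in disease_gene layer: ", u, " -- ", v,
        " connects two ", type_of[[u]], " nodes")
  }
  ids <- sort(ls(type_of))
  nodes <- data.frame(id = ids,
    type = vapply(ids, function(n) type_of[[n]], ""),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(nodes = nodes, layers = layers),
    class = "multiplex_network")
}

#' Read a multiplex network from edge-list files
#'
#' Each layer file is TSV `u<TAB>v[<TAB>weight]` without header; the optional
#' node-type file is TSV `node<TAB>type`.
#'
#' @param disease_disease,disease_gene,protein_protein Paths to the layer
#'   edge lists.
#' @param node_types Optional path to a node-type table.
#' @return A [multiplex_network()].
#' @export
read_network <- function(disease_disease, disease_gene, protein_protein,
                         node_types = NULL) {
  read_layer <- function(path) {
    if (file.size(path) == 0) return(data.frame(u = character(0),
      v = character(0), weight = numeric(0)))
    read.delim(path, header = FALSE, sep = "\t", quote = "",
      colClasses = "character")
  }
  nt <- NULL
  if (!is.null(node_types)) {
    nt <- read.delim(node_types, header = FALSE, sep = "\t", quote = "",
      colClasses = "character")
    names(nt)[1:2] <- c("node", "type")
  }
  multiplex_network(read_layer(disease_disease), read_layer(disease_gene),
    read_layer(protein_protein), node_types = nt)
}

#' Degree-normalized transition matrix of a multiplex network
#'
#' Aggregates the three layers by summing their weighted adjacencies over the
#' union node set (unit layer weights by default) and column-normalizes:
#' \eqn{M = A D^{-1}} with `D` the diagonal of column sums, so each
#' non-isolated column of `M` is a probability distribution. Isolated nodes
#' get zero columns and are flagged.
#'
#' @param net A [multiplex_network()].
#' @param layer_weights Named or positional numeric vector of length 3
#'   weighting the layers in the aggregation (default all 1).
#' @return A `transition_matrix`: list with sparse matrix `M`, the `nodes`
#'   table and the ids of `isolated` nodes.
#' @export
build_transition <- function(net, layer_weights = c(1, 1, 1)) {
  stopifnot(inherits(net, "multiplex_network"))
  n <- nrow(net$nodes)
  if (n == 0L) stop("empty network")
  stopifnot(length(layer_weights) == 3, all(layer_weights >= 0))
  idx <- seq_len(n)
  names(idx) <- net$nodes$id
  A <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
    dims = c(n, n))
  for (k in seq_along(net$layers)) {
    e <- net$layers[[k]]
    if (nrow(e) == 0L) next
    A <- A + Matrix::sparseMatrix(i = c(idx[e$u], idx[e$v]),
      j = c(idx[e$v], idx[e$u]), x = rep(e$weight * layer_weights[k], 2),
      dims = c(n, n))
  }
  deg <- Matrix::colSums(A)
  isolated <- net$nodes$id[deg == 0]
  inv <- ifelse(deg > 0, 1 / deg, 0)
  M <- A %*% Matrix::Diagonal(n, inv)
  dimnames(M) <- list(net$nodes$id, net$nodes$id)
  structure(list(M = M, nodes = net$nodes, isolated = isolated),
    class = "transition_matrix")
}

make_p0 <- function(tm, seeds) {
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L) stop("seed set is empty")
  missing <- setdiff(seeds, tm$nodes$id)
  if (length(missing))
    stop("seed node(s) not in network: ", paste(missing, collapse = ", "))
  p0 <- numeric(nrow(tm$nodes))
  names(p0) <- tm$nodes$id
  p0[seeds] <- 1 / length(seeds)
  p0
}

#' Random walk with restart by power iteration
#'
#' Iterates \eqn{p_{t+1} = (1 - r) M p_t + r p_0} with \eqn{p_0} uniform over
#' the seed nodes until the L1 change drops below `tol` or `max_iter` is
#' reached. The stationary distribution measures proximity of every node to
#' the seeds. Because isolated nodes have zero columns, the vector is
#' renormalized to total mass 1 after each update.
#'
#' @param tm A [build_transition()] result.
#' @param seeds Character vector of seed node ids (e.g. a disease and a gene
#'   known to be associated with it).
#' @param restart Restart probability in (0, 1\]; default 0.7.
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter Iteration cap (default 1000).
#' @return An `rwr_result`: list with probability vector `p` (named, sums to
#'   1), `seeds`, `restart`, `iterations`, `converged`, and the `nodes`
#'   table.
#' @export
rwr <- function(tm, seeds, restart = 0.7, tol = 1e-10, max_iter = 1000) {
  stopifnot(inherits(tm, "transition_matrix"))
  if (restart <= 0 || restart > 1) stop("restart must lie in (0, 1]")
  p0 <- make_p0(tm, seeds)
  p <- p0
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    p_new <- as.numeric((1 - restart) * (tm$M %*% p)) + restart * p0
    s <- sum(p_new)
    if (s > 0 && abs(s - 1) > 1e-14) p_new <- p_new / s
    delta <- sum(abs(p_new - p))
    p <- p_new
    iterations <- it
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  names(p) <- tm$nodes$id
  structure(list(p = p, seeds = unique(as.character(seeds)),
    restart = restart, iterations = iterations, converged = converged,
    nodes = tm$nodes), class = "rwr_result")
}

#' Closed-form random walk with restart
#'
#' Solves \eqn{p = r (I - (1 - r) M)^{-1} p_0} by a direct linear solve.
#' This is the exact stationary distribution and serves as the oracle for the
#' power-iteration solver [rwr()].
#'
#' @inheritParams rwr
#' @return Named probability vector over nodes.
#' @export
rwr_exact <- function(tm, seeds, restart = 0.7) {
  stopifnot(inherits(tm, "transition_matrix"))
  if (restart <= 0 || restart > 1) stop("restart must lie in (0, 1]")
  p0 <- make_p0(tm, seeds)
  n <- length(p0)
  A <- diag(n) - (1 - restart) * as.matrix(tm$M)
  p <- tryCatch(solve(A, restart * p0),
    error = function(e) stop("singular linear system: ", conditionMessage(e),
      call. = FALSE))
  names(p) <- tm$nodes$id
  p
}

#' Top-ranked candidate nodes from an RWR run
#'
#' Ranks nodes by stationary probability (descending; ties broken by node id)
#' optionally restricted to one node type, excluding seed nodes by default --
#' the candidates "near" the seeds that the walk surfaces.
#'
#' @param result An [rwr()] result (must have converged).
#' @param k Number of candidates (default 15, the conventional short-list
#'   size); capped at the number of available nodes.
#' @param node_type Optional filter: `"gene"` or `"disease"`.
#' @param exclude_seeds Drop seed nodes from the ranking (default `TRUE`).
#' @return Data frame `node`, `type`, `probability`, sorted.
#' @export
top_candidates <- function(result, k = 15, node_type = NULL,
                           exclude_seeds = TRUE) {
  stopifnot(inherits(result, "rwr_result"))
  if (!result$converged)
    stop("RWR did not converge; candidates would be unreliable")
  tab <- data.frame(node = result$nodes$id, type = result$nodes$type,
    probability = unname(result$p[result$nodes$id]),
    stringsAsFactors = FALSE)
  if (!is.null(node_type)) tab <- tab[tab$type == node_type, , drop = FALSE]
  if (exclude_seeds) tab <- tab[!(tab$node %in% result$seeds), , drop = FALSE]
  tab <- tab[order(-tab$probability, tab$node), , drop = FALSE]
  rownames(tab) <- NULL
  head(tab, k)
}
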