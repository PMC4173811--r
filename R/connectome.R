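# Synthetic 66-region connectome: a stand-in for empirical
# structural-connectivity and fibre-distance matrices, with two mirrored
# hemispheres, six planted clusters and strong central homologous links.
# Purely synthetic - generated from a seed, not derived from any
# empirical dataset.

#' Synthetic two-hemisphere connectome fixture
#'
#' Generates a 66-node weighted network emulating the gross organisation
#' of a cortical connectome: two 33-node hemispheres (nodes 1-33 left,
#' 34-66 right, homolog of node `i` at `67 - i`), six planted clusters
#' of sizes 11, 5, 8, 14, 5 and 11 plus 12 unclustered ("individual")
#' nodes, with the central cluster (cluster 4, nodes 27-40) given the
#' largest weights and spanning both hemispheres through strong
#' homologous links. Node coordinates are drawn in 3-D with mirrored
#' hemispheres and distances are Euclidean. The dynamics matrix `C` is
#' row-normalised (connected rows sum to 1); the raw pre-normalisation
#' weights are returned as `C_raw` for cluster-level strength summaries.
#'
#' @param seed Integer seed.
#' @param n_nodes Number of nodes; must currently be 66.
#' @return List with `C` (row-normalised weights), `C_raw` (raw
#'   weights), `L` (symmetric distance matrix, zero diagonal),
#'   `hemisphere` (labels `"L"`/`"R"`), `clusters` (labels `"cluster1"`
#'   ... `"cluster6"`, `"individual"`), `coords` (66 x 3).
#' @examples
#' cx <- synthetic_connectome(seed = 1)
#' cluster_summary(cx$C_raw, cx$clusters)
#' @export
synthetic_connectome <- function(seed = 1L, n_nodes = 66L) {
  if (n_nodes != 66L)
    stop("the synthetic connectome is defined for 66 nodes")
  with_seed(seed, {
    hemisphere <- rep(c("L", "R"), each = 33L)
    clusters <- rep("individual", 66L)
    clusters[7:17] <- "cluster1"
    clusters[18:22] <- "cluster2"
    clusters[c(23:26, 41:44)] <- "cluster3"
    clusters[27:40] <- "cluster4"
    clusters[45:49] <- "cluster5"
    clusters[50:60] <- "cluster6"

    # mirrored 3-D coordinates; homolog of i is 67 - i
    left <- cbind(runif(33, -60, -8), runif(33, -50, 50), runif(33, -40, 40))
    right <- left[33:1, , drop = FALSE] * matrix(c(-1, 1, 1), 33, 3,
                                                 byrow = TRUE) +
      matrix(rnorm(99, 0, 2), 33, 3)
    coords <- rbind(left, right)
    L <- as.matrix(dist(coords))
    diag(L) <- 0

    W <- matrix(0, 66, 66)
    add_edge <- function(i, j, w) {
      W[i, j] <<- w; W[j, i] <<- w
    }
    # dense strong intra-cluster connectivity; central cluster heaviest
    for (cl in paste0("cluster", 1:6)) {
      members <- which(clusters == cl)
      scale <- if (cl == "cluster4") 3 else 1.2
      for (a in seq_along(members)) {
        for (b in seq_len(a - 1L)) {
          if (runif(1) < 0.75)
            add_edge(members[a], members[b], scale * runif(1, 0.5, 1))
        }
      }
    }
    # strong central homologous (cross-hemisphere) links in cluster 4
    for (i in 27:33) add_edge(i, 67L - i, 3 * runif(1, 0.8, 1.2))
    # sparse weak background connections across the whole network
    for (i in 1:65) {
      for (j in (i + 1L):66L) {
        if (W[i, j] == 0 && runif(1) < 0.08)
          add_edge(i, j, runif(1, 0.05, 0.3))
      }
    }
    rs <- rowSums(W)
    C <- W / ifelse(rs > 0, rs, 1)
    list(C = C, C_raw = W, L = L, hemisphere = hemisphere,
         clusters = clusters, coords = coords)
  })
}
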