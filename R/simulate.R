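#' TN93 substitution-model parameters
#'
#' Bundles the rates and base frequencies of the Tamura-Nei model used by the
#' sequence simulator: two transition rate multipliers (A/G and C/T) relative
#' to a transversion rate of 1, and the stationary base frequencies. The rate
#' matrix is normalised so branch lengths are expected substitutions/site.
#' Defaults (transition/transversion multipliers of 4, mildly AT-rich
#' frequencies) are typical of ribosomal and mitochondrial barcode markers.
#'
#' @param kappa1 A/G transition rate multiplier (> 0).
#' @param kappa2 C/T transition rate multiplier (> 0).
#' @param freqs Stationary base frequencies, named `A`, `C`, `G`, `T`,
#'   summing to 1.
#' @return A `tn93_params` list.
#' @export
tn93_params <- function(kappa1 = 4, kappa2 = 4,
                        freqs = c(A = 0.26, C = 0.22, G = 0.24, T = 0.28)) {
  freqs <- freqs[c("A", "C", "G", "T")]
  if (anyNA(freqs) || any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-9)
    stop_format("`freqs` must be positive, named A/C/G/T and sum to 1")
  if (kappa1 <= 0 || kappa2 <= 0)
    stop_format("transition rate multipliers must be positive")
  structure(list(kappa1 = kappa1, kappa2 = kappa2, freqs = freqs),
            class = "tn93_params")
}

# normalised TN93 rate matrix (rows/cols in A,C,G,T order; mean rate 1)
tn93_rate_matrix <- function(params) {
  f <- params$freqs
  rate <- matrix(1, 4, 4, dimnames = list(names(f), names(f)))
  rate["A", "G"] <- rate["G", "A"] <- params$kappa1
  rate["C", "T"] <- rate["T", "C"] <- params$kappa2
  Q <- rate * rep(f, each = 4)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(f * diag(Q))
  Q / mu
}

# P(t) = exp(Qt) via the symmetrised eigendecomposition of a reversible Q
tn93_transition_prob <- function(Q, freqs, t) {
  s <- sqrt(freqs)
  S <- Q * outer(s, 1 / s)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  P <- outer(1 / s, s) * (e$vectors %*% (exp(e$values * t) * t(e$vectors)))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate a host tree under a Yule process
#'
#' Draws a pure-birth (Yule) tree and rescales it so every root-to-tip path
#' equals `depth` substitutions/site — a stand-in for a clade of divergent
#' host lineages of a given overall depth.
#'
#' @param n_tips Number of tips (>= 4).
#' @param seed Integer seed (optional).
#' @param depth Root-to-tip path length in substitutions/site (default 0.15).
#' @return An ultrametric `phylo` tree with tips `t01`, `t02`, ...
#' @export
sample_host_tree <- function(n_tips, seed = NULL, depth = 0.15) {
  n_tips <- as.integer(n_tips)
  if (n_tips < 4L) stop_format("need at least 4 tips, got %d", n_tips)
  if (depth < 0) stop_format("`depth` must be non-negative")
  tr <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  tr$tip.label <- sprintf("t%02d", seq_len(n_tips))
  h <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- if (h > 0) tr$edge.length * (depth / h) else tr$edge.length * 0
  tr
}

# prune tip `tip` and regraft it at a uniformly chosen point of a uniformly
# chosen edge, keeping the tree ultrametric
regraft_tip <- function(tree, tip, total_depth) {
  tr2 <- ape::drop.tip(tree, tip)
  depths <- ape::node.depth.edgelength(tr2)
  e <- sample.int(nrow(tr2$edge), 1L)
  w <- tr2$edge[e, 2L]
  len <- tr2$edge.length[e]
  u <- stats::runif(1)
  attach_depth <- depths[w] - u * len        # height of the attachment point
  phytools::bind.tip(tr2, tip, edge.length = max(total_depth - attach_depth, 0),
                     where = w, position = u * len)
}

#' Derive a parasite tree with a controlled number of host shifts
#'
#' Starts from a copy of the host tree (perfect co-divergence) with tips
#' relabeled `p(host tip)`, then applies `n_shifts` random tip
#' prune-and-regraft moves, each moving one distinct parasite tip to a
#' uniformly chosen position elsewhere in the tree — the phylogenetic
#' signature of a host shift followed by specialisation. Moved tips keep
#' their host association, which is exactly what makes the corresponding
#' links incongruent. Branch lengths are finally multiplied by
#' `rate_ratio` (parasite/host substitution rate; default 1).
#'
#' @param host_tree Ultrametric `phylo` from [sample_host_tree()].
#' @param n_shifts Number of host shifts, between 0 and `n_tips - 2`.
#' @param seed Integer seed (optional).
#' @param rate_ratio Parasite/host branch-length ratio (default 1).
#' @return List with `tree` (the parasite `phylo`) and `shifted` (labels of
#'   the moved parasite tips).
#' @export
derive_parasite_tree <- function(host_tree, n_shifts, seed = NULL,
                                 rate_ratio = 1) {
  n_tips <- length(host_tree$tip.label)
  n_shifts <- as.integer(n_shifts)
  if (n_shifts < 0L || n_shifts > n_tips - 2L)
    stop_format("n_shifts must be in [0, %d], got %d", n_tips - 2L, n_shifts)
  tr <- host_tree
  tr$tip.label <- paste0("p", host_tree$tip.label)
  shifted <- character(0)
  if (n_shifts > 0L) {
    total_depth <- max(ape::node.depth.edgelength(tr))
    with_seed(seed, {
      shifted <- sample(tr$tip.label, n_shifts)
      for (tip in shifted) {
        moved <- FALSE
        for (try in 1:25) {
          cand <- regraft_tip(tr, tip, total_depth)
          if (suppressWarnings(ape::dist.topo(cand, tr)) > 0) {
            tr <- cand
            moved <- TRUE
            break
          }
        }
        if (!moved)
          stop_format("could not find a topology-changing regraft for '%s' after 25 tries; use another seed",
                      tip)
      }
    })
  }
  tr$edge.length <- tr$edge.length * rate_ratio
  list(tree = tr, shifted = shifted)
}

#' Evolve sequences along a tree under the TN93 model
#'
#' Samples a root sequence from the stationary base frequencies and evolves
#' it along every branch by site-independent substitution with transition
#' probabilities \eqn{P(t) = e^{Qt}}, where `Q` is the normalised TN93 rate
#' matrix and `t` the branch length in substitutions/site.
#'
#' @param tree A `phylo` with branch lengths in substitutions/site.
#' @param length Sequence length in sites (>= 100).
#' @param params A [tn93_params()] object.
#' @param seed Integer seed (optional).
#' @return A [partial_alignment] of the tip sequences (full coverage).
#' @export
evolve_sequences <- function(tree, length, params = tn93_params(),
                             seed = NULL) {
  stopifnot(inherits(params, "tn93_params"))
  length <- as.integer(length)
  if (length < 100L)
    stop_format("sequence length must be at least 100 sites, got %d", length)
  Q <- tn93_rate_matrix(params)
  f <- params$freqs
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  root <- n_tip + 1L

  states <- with_seed(seed, {
    st <- matrix(NA_integer_, n_tip + n_node, length)
    st[root, ] <- sample.int(4L, length, replace = TRUE, prob = f)
    edges <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(edges$edge))) {
      par <- edges$edge[e, 1L]; chl <- edges$edge[e, 2L]
      t_e <- edges$edge.length[e]
      if (t_e <= 0) {
        st[chl, ] <- st[par, ]
        next
      }
      P <- tn93_transition_prob(Q, f, t_e)
      child <- integer(length)
      for (s in 1:4) {
        idx <- which(st[par, ] == s)
        if (length(idx) > 0L)
          child[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[s, ])
      }
      st[chl, ] <- child
    }
    st
  })
  bases <- names(NUC_CODE)
  residues <- apply(states[seq_len(n_tip), , drop = FALSE], 1L,
                    function(r) paste(bases[r], collapse = ""))
  partial_alignment(residues, labels = tree$tip.label)
}

#' Truncate sequences to primer-anchored fragments
#'
#' Emulates marker fragments of heterogeneous length sharing a 5' forward
#' primer: each sequence's coverage is replaced by `[0, drawn length)`, the
#' remainder becoming padding (`?`). Fragment lengths are drawn from
#' `length_mix`, whose names are fragment lengths in sites (or `"full"`) and
#' whose values are probabilities.
#'
#' @param aln A [partial_alignment] (typically full-length simulated
#'   sequences).
#' @param length_mix Named probability vector, e.g.
#'   `c("350" = 1/6, "530" = 1/6, full = 2/3)`.
#' @param seed Integer seed (optional).
#' @return A [partial_alignment] with truncated coverages.
#' @export
truncate_fragments <- function(aln,
                               length_mix = c("350" = 1/6, "530" = 1/6,
                                              full = 2/3),
                               seed = NULL) {
  stopifnot(inherits(aln, "partial_alignment"))
  if (is.null(names(length_mix)) || any(length_mix < 0) ||
      abs(sum(length_mix) - 1) > 1e-9)
    stop_format("`length_mix` must be a named probability vector summing to 1")
  lens <- ifelse(names(length_mix) == "full", aln$columns,
                 suppressWarnings(as.integer(names(length_mix))))
  if (anyNA(lens))
    stop_format("`length_mix` names must be integers or 'full'")
  if (any(lens > aln$columns))
    stop_format("fragment length %d exceeds alignment length %d",
                max(lens), aln$columns)
  if (any(lens < 1L)) stop_format("fragment lengths must be positive")
  drawn <- with_seed(seed,
    lens[sample.int(length(lens), length(aln$labels), replace = TRUE,
                    prob = length_mix)])
  residues <- vapply(seq_along(aln$labels), function(i) {
    paste0(substr(aln$residues[[i]], 1L, drawn[i]),
           strrep("?", aln$columns - drawn[i]))
  }, character(1))
  partial_alignment(residues, labels = aln$labels)
}

#' Simulate a complete co-diversification scenario
#'
#' Generates all the ground-truth ingredients of a host-parasite
#' co-diversification study: a Yule host tree of divergent lineages, a
#' parasite tree tracking it except for `n_shifts` host shifts, host and
#' parasite sequences evolved under TN93, optional truncation of the
#' parasite sequences to primer-anchored fragments, and the true
#' host-parasite link list with the shifted subset marked. Sub-seeds for
#' each stage are derived from `seed` by fixed offsets, so the whole
#' scenario is reproducible from one integer.
#'
#' @param n_tips Number of host lineages (>= 4; default 16).
#' @param n_shifts Number of host shifts (default 0).
#' @param seed Integer seed (optional).
#' @param depth Host tree root-to-tip depth in substitutions/site
#'   (default 0.15).
#' @param rate_ratio Parasite/host substitution rate ratio (default 1).
#' @param host_length,parasite_length Sequence lengths in sites (defaults
#'   650 — a COI barcode — and 800 — the longest SSU fragment).
#' @param params A [tn93_params()] object.
#' @param fragment_mix Passed to [truncate_fragments()] for the parasite
#'   alignment; `NULL` keeps full-length parasites.
#' @return A `cophylo_scenario`: list with `host_tree`, `parasite_tree`,
#'   `true_links` (data frame `host`, `parasite`, one per parasite tip),
#'   `shifted` (parasite labels created by host shifts), `host_aln`,
#'   `parasite_aln` and `params`.
#' @export
simulate_scenario <- function(n_tips = 16L, n_shifts = 0L, seed = NULL,
                              depth = 0.15, rate_ratio = 1,
                              host_length = 650L, parasite_length = 800L,
                              params = tn93_params(),
                              fragment_mix = NULL) {
  off <- function(k) if (is.null(seed)) NULL else as.integer(seed) + k
  host_tree <- sample_host_tree(n_tips, seed = off(1L), depth = depth)
  par_ <- derive_parasite_tree(host_tree, n_shifts, seed = off(2L),
                               rate_ratio = rate_ratio)
  host_aln <- evolve_sequences(host_tree, host_length, params, seed = off(3L))
  parasite_aln <- evolve_sequences(par_$tree, parasite_length, params,
                                   seed = off(4L))
  if (!is.null(fragment_mix))
    parasite_aln <- truncate_fragments(parasite_aln, fragment_mix,
                                       seed = off(5L))
  true_links <- data.frame(host = host_tree$tip.label,
                           parasite = paste0("p", host_tree$tip.label),
                           stringsAsFactors = FALSE)
  structure(list(host_tree = host_tree, parasite_tree = par_$tree,
                 true_links = true_links, shifted = par_$shifted,
                 host_aln = host_aln, parasite_aln = parasite_aln,
                 params = list(n_tips = n_tips, n_shifts = n_shifts,
                               seed = seed, depth = depth,
                               rate_ratio = rate_ratio,
                               host_length = host_length,
                               parasite_length = parasite_length,
                               kappa1 = params$kappa1, kappa2 = params$kappa2,
                               freqs = as.list(params$freqs),
                               fragment_mix = as.list(fragment_mix))),
            class = "cophylo_scenario")
}

#' @export
print.cophylo_scenario <- function(x, ...) {
  cat(sprintf("cophylo_scenario: %d hosts, %d links, %d host shift(s)\n",
              length(x$host_tree$tip.label), nrow(x$true_links),
              length(x$shifted)))
  invisible(x)
}

#' Write a simulated scenario to files
#'
#' Emits the scenario as plain-text files: host and parasite FASTA
#' alignments, Newick trees, the true link list and shifted-link subset as
#' TSV, and the simulation parameters as JSON.
#'
#' @param scenario A `cophylo_scenario` from [simulate_scenario()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
emit_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "cophylo_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    host_fasta = file.path(dir, "host.fasta"),
    parasite_fasta = file.path(dir, "parasite.fasta"),
    host_tree = file.path(dir, "host_tree.nwk"),
    parasite_tree = file.path(dir, "parasite_tree.nwk"),
    links = file.path(dir, "links.tsv"),
    shifted = file.path(dir, "shifted_links.tsv"),
    params = file.path(dir, "params.json")
  )
  write_fasta_alignment(scenario$host_aln, paths[["host_fasta"]])
  write_fasta_alignment(scenario$parasite_aln, paths[["parasite_fasta"]])
  ape::write.tree(scenario$host_tree, paths[["host_tree"]])
  ape::write.tree(scenario$parasite_tree, paths[["parasite_tree"]])
  utils::write.table(scenario$true_links, paths[["links"]], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  shifted_links <- scenario$true_links[
    scenario$true_links$parasite %in% scenario$shifted, , drop = FALSE]
  utils::write.table(shifted_links, paths[["shifted"]], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(scenario$params, paths[["params"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
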