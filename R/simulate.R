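#' Simulation configuration
#'
#' Describes the generative world used for validation: a species tree with
#' branch lengths in expected substitutions per site, within-species
#' coalescent polymorphism, motif instances planted at the root, an
#' elevated (or reduced) substitution rate inside planted sites, and
#' species-level deletions outside sites.
#'
#' @param seed integer seed; the same config yields byte-identical output.
#' @param tree [ape::phylo] with branch lengths, or a newick string.
#' @param n_haplotypes haplotypes per species: single integer or named vector.
#' @param length alignment columns before indels.
#' @param theta_within per-site population mutation rate for the
#'   within-species coalescent (theta = 4 N mu per site).
#' @param tfbs_rate_multiplier per-column branch substitution-rate multiplier
#'   inside planted sites (r = 1: neutral null).
#' @param library `motif_library` providing plantable exact sites.
#' @param n_planted_sites motif instances planted at the root.
#' @param indel_rate expected species-level deletions per column.
#' @param indel_mean_len mean deletion length (geometric).
#' @param turnover_gain,turnover_loss expected explicit binding-site gain /
#'   loss events per branch (default 0): a gain writes a library site into a
#'   site-free stretch, a loss substitutes one base inside an existing
#'   planted site; both are recorded in the truth with their intervals.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed, tree, n_haplotypes = 4L, length = 1000L,
                       theta_within = 0.005, tfbs_rate_multiplier = 1,
                       library = toy_motif_library(), n_planted_sites = 10L,
                       indel_rate = 0, indel_mean_len = 3,
                       turnover_gain = 0, turnover_loss = 0) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  sp <- tree$tip.label
  if (length(n_haplotypes) == 1L)
    n_haplotypes <- stats::setNames(rep(n_haplotypes, length(sp)), sp)
  if (!all(sp %in% names(n_haplotypes)))
    stop("n_haplotypes must cover every species")
  if (tfbs_rate_multiplier <= 0) stop("rate multiplier must be positive")
  structure(list(seed = as.integer(seed), tree = tree,
                 n_haplotypes = n_haplotypes[sp], length = as.integer(length),
                 theta_within = theta_within,
                 tfbs_rate_multiplier = tfbs_rate_multiplier,
                 library = library, n_planted_sites = as.integer(n_planted_sites),
                 indel_rate = indel_rate, indel_mean_len = indel_mean_len,
                 turnover_gain = turnover_gain, turnover_loss = turnover_loss),
            class = "sim_config")
}

# Kingman coalescent for n haplotypes: mutations with carrier sets.
# theta_total = theta per locus (not per site).  Returns a list of integer
# carrier vectors, ordered from oldest epoch to the present.
coalescent_mutations <- function(n, theta_total) {
  if (n < 2L || theta_total <= 0) return(list())
  lineages <- as.list(seq_len(n))
  muts <- list()   # collected tipward epoch first
  k <- n
  while (k > 1L) {
    t <- stats::rexp(1L, rate = k * (k - 1L) / 2)
    for (ln in lineages) {
      nm <- stats::rpois(1L, theta_total / 2 * t)
      if (nm > 0L) for (i in seq_len(nm)) muts[[length(muts) + 1L]] <- ln
    }
    pair <- sample.int(k, 2L)
    merged <- c(lineages[[pair[1L]]], lineages[[pair[2L]]])
    lineages <- c(lineages[-pair], list(merged))
    k <- k - 1L
  }
  rev(muts)  # apply oldest first
}

#' Simulate one population sample under the neutral coalescent
#'
#' Draws a Kingman genealogy for `n` haplotypes, places mutations on it at
#' rate `theta_per_site * length / 2` per unit coalescent time, and applies
#' them to a uniform-random ancestral sequence.  This is the within-species
#' layer of [simulate_dataset()] exposed on its own; under neutrality the
#' site-frequency spectrum (and hence Tajima's D, Fu and Li's D) has its
#' theoretical null behaviour.
#'
#' @param n haplotypes to sample (>= 2).
#' @param theta_per_site population mutation rate per site.
#' @param length sequence length in columns.
#' @param species_id species label for the sampled haplotypes.
#' @param seed optional integer seed.
#' @return a `haplotype_alignment` of one species.
#' @export
simulate_population <- function(n, theta_per_site, length, species_id = "pop",
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, length, replace = TRUE)
  haps <- replicate(n, anc, simplify = FALSE)
  for (carriers in coalescent_mutations(n, theta_per_site * length)) {
    col <- sample.int(length, 1L)
    to <- sample(setdiff(bases, haps[[carriers[1L]]][col]), 1L)
    for (h in carriers) haps[[h]][col] <- to
  }
  haplotype_alignment(vapply(haps, paste, "", collapse = ""),
                      paste0(species_id, "_h", seq_len(n)),
                      rep(species_id, n))
}

#' Simulate a multi-species, multi-haplotype regulatory alignment
#'
#' Draws a uniform root sequence, plants non-overlapping motif instances
#' from the library, evolves species sequences along the tree under a
#' Jukes-Cantor-style model with a per-column rate multiplier inside planted
#' sites, layers within-species coalescent polymorphism on each species, and
#' finally applies species-level deletions outside planted sites.  Every
#' branch substitution and haplotype mutation is recorded in the truth.
#'
#' @param config a [sim_config()].
#' @return list with `alignment` (`haplotype_alignment`), `truth_track`
#'   (planted sites as an `annotation_track`, method `TRUTH`), `tree`, and
#'   `truth` (root sequence, per-branch events, planted intervals, species
#'   sequences, haplotype mutations, indels, config).
#' @export
simulate_dataset <- function(config) {
  set.seed(config$seed)
  L <- config$length
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, L, replace = TRUE)

  # plant motif instances, non-overlapping
  sites <- config$library$exact_sites
  if (config$n_planted_sites > 0L && nrow(sites) == 0L)
    stop("config error: no exact sites available to plant")
  planted <- data.frame(start = integer(), end = integer(), factor = character())
  mask <- logical(L)
  for (i in seq_len(config$n_planted_sites)) {
    k <- sample.int(nrow(sites), 1L)
    w <- nchar(sites$site[k])
    if (w > L) stop("config error: motif longer than sequence")
    for (try in 1:200) {
      st <- sample.int(L - w + 1L, 1L) - 1L
      if (!any(mask[(st + 1L):(st + w)])) {
        root[(st + 1L):(st + w)] <- strsplit(sites$site[k], "")[[1L]]
        mask[(st + 1L):(st + w)] <- TRUE
        planted <- rbind(planted, data.frame(start = st, end = st + w,
                                             factor = sites$factor[k]))
        break
      }
    }
  }

  tree <- config$tree
  sc <- tree_scaffold(tree)
  node_seq <- vector("list", sc$nnode)
  node_sites <- vector("list", sc$nnode)   # planted/gained sites alive at node
  node_seq[[sc$root]] <- root
  node_sites[[sc$root]] <- planted
  branch_events <- list()
  turnover <- NULL
  elen <- stats::setNames(tree$edge.length, tree$edge[, 2L])
  for (nd in sc$preorder) {
    p <- sc$parent[nd]
    if (is.na(p)) next
    b <- elen[[as.character(nd)]]
    seq <- node_seq[[p]]
    cur_sites <- node_sites[[p]]
    rate <- b * ifelse(mask, config$tfbs_rate_multiplier, 1)
    psub <- 1 - exp(-rate)
    hit <- which(stats::runif(L) < psub)
    ev <- NULL
    if (length(hit)) {
      from <- seq[hit]
      to <- vapply(from, function(fb) sample(setdiff(bases, fb), 1L), "")
      seq[hit] <- to
      ev <- data.frame(column = hit - 1L, branch = sc$labels[nd],
                       from = from, to = to)
    }
    # explicit site losses: one substitution inside a surviving site
    n_loss <- stats::rpois(1L, config$turnover_loss)
    for (i in seq_len(min(n_loss, nrow(cur_sites)))) {
      # only sites still intact (not already broken by background noise)
      intact <- which(vapply(seq_len(nrow(cur_sites)), function(k)
        paste(seq[(cur_sites$start[k] + 1L):cur_sites$end[k]], collapse = "") %in%
          sites$site, TRUE))
      if (length(intact) == 0L) break
      k <- if (length(intact) == 1L) intact else sample(intact, 1L)
      s <- cur_sites[k, ]
      col <- sample(s$start:(s$end - 1L), 1L) + 1L
      from_b <- seq[col]
      to_b <- sample(setdiff(bases, from_b), 1L)
      seq[col] <- to_b
      ev <- rbind(ev, data.frame(column = col - 1L, branch = sc$labels[nd],
                                 from = from_b, to = to_b))
      turnover <- rbind(turnover, data.frame(
        branch = sc$labels[nd], type = "loss", start = s$start, end = s$end,
        factor = s$factor))
      cur_sites <- cur_sites[-k, , drop = FALSE]
    }
    # explicit site gains: write a library site into a site-free stretch
    n_gain <- stats::rpois(1L, config$turnover_gain)
    occupied <- mask
    for (k in seq_len(nrow(cur_sites)))
      occupied[(cur_sites$start[k] + 1L):cur_sites$end[k]] <- TRUE
    for (i in seq_len(n_gain)) {
      k <- sample.int(nrow(sites), 1L)
      site_seq <- strsplit(sites$site[k], "")[[1L]]
      w <- length(site_seq)
      for (try in 1:100) {
        st <- sample.int(L - w + 1L, 1L) - 1L
        span <- (st + 1L):(st + w)
        if (any(occupied[span])) next
        diff <- which(seq[span] != site_seq)
        if (length(diff) == 0L) next    # already a site here by chance
        for (dcol in span[diff])
          ev <- rbind(ev, data.frame(column = dcol - 1L, branch = sc$labels[nd],
                                     from = seq[dcol],
                                     to = site_seq[dcol - st]))
        seq[span] <- site_seq
        occupied[span] <- TRUE
        cur_sites <- rbind(cur_sites, data.frame(start = st, end = st + w,
                                                 factor = sites$factor[k]))
        turnover <- rbind(turnover, data.frame(
          branch = sc$labels[nd], type = "gain", start = st, end = st + w,
          factor = sites$factor[k]))
        break
      }
    }
    branch_events[[sc$labels[nd]]] <- ev
    node_seq[[nd]] <- seq
    node_sites[[nd]] <- cur_sites
  }
  species_seqs <- lapply(seq_len(sc$ntip), function(i) node_seq[[i]])
  names(species_seqs) <- tree$tip.label

  # within-species coalescent polymorphism
  hap_seqs <- list(); hap_sp <- character(); hap_muts <- list()
  for (s in tree$tip.label) {
    nh <- config$n_haplotypes[[s]]
    haps <- replicate(nh, species_seqs[[s]], simplify = FALSE)
    muts <- coalescent_mutations(nh, config$theta_within * L)
    mlog <- NULL
    for (carriers in muts) {
      col <- sample.int(L, 1L)
      cur <- haps[[carriers[1L]]][col]
      to <- sample(setdiff(bases, cur), 1L)
      for (h in carriers) haps[[h]][col] <- to
      mlog <- rbind(mlog, data.frame(column = col - 1L, from = cur, to = to,
                                     carriers = paste(sort(carriers),
                                                      collapse = ",")))
    }
    hap_muts[[s]] <- mlog
    for (h in seq_len(nh)) {
      hap_seqs[[paste0(s, "_h", h)]] <- haps[[h]]
      hap_sp <- c(hap_sp, s)
    }
  }

  # species-level deletions outside planted sites
  indels <- NULL
  if (config$indel_rate > 0) {
    for (s in tree$tip.label) {
      k <- stats::rpois(1L, config$indel_rate * L)
      for (i in seq_len(k)) {
        len <- stats::rgeom(1L, 1 / config$indel_mean_len) + 1L
        for (try in 1:20) {
          st <- sample.int(max(L - len, 1L), 1L) - 1L
          span <- (st + 1L):min(st + len, L)
          if (!any(mask[span])) {
            for (h in names(hap_seqs)[hap_sp == s]) hap_seqs[[h]][span] <- "-"
            indels <- rbind(indels, data.frame(species = s, start = st,
                                               end = st + length(span)))
            break
          }
        }
      }
    }
  }

  aln <- haplotype_alignment(vapply(hap_seqs, paste, "", collapse = ""),
                             names(hap_seqs), hap_sp)
  truth_track <- annotation_track(
    if (nrow(planted)) cbind(planted, strand = ".") else NULL,
    "TRUTH", L, "alignment_columns")
  truth <- list(root = paste(root, collapse = ""),
                branch_events = branch_events,
                planted_sites = planted, turnover = turnover,
                species_seqs = vapply(species_seqs, paste, "", collapse = ""),
                hap_mutations = hap_muts, indels = indels, config = config)
  list(alignment = aln, truth_track = truth_track, tree = tree, truth = truth)
}

#' Replay recorded truth events from the root
#'
#' Re-derives every species sequence by applying the recorded per-branch
#' substitutions to the root along the tree, and every haplotype by applying
#' the recorded coalescent mutations to its species sequence; any mismatch
#' with the emitted sequences raises an internal-consistency error.
#'
#' @param truth the `truth` component of a [simulate_dataset()] result.
#' @param alignment optional emitted `haplotype_alignment` to verify as well
#'   (non-gap characters must match the replayed haplotypes).
#' @return named character vector of replayed species sequences, invisibly.
#' @export
replay_truth <- function(truth, alignment = NULL) {
  tree <- truth$config$tree
  sc <- tree_scaffold(tree)
  node_seq <- vector("list", sc$nnode)
  node_seq[[sc$root]] <- strsplit(truth$root, "")[[1L]]
  for (nd in sc$preorder) {
    p <- sc$parent[nd]
    if (is.na(p)) next
    seq <- node_seq[[p]]
    ev <- truth$branch_events[[sc$labels[nd]]]
    if (!is.null(ev) && nrow(ev)) {
      if (any(seq[ev$column + 1L] != ev$from))
        stop("internal consistency error: event log does not match parent sequence")
      seq[ev$column + 1L] <- ev$to
    }
    node_seq[[nd]] <- seq
  }
  out <- vapply(seq_len(sc$ntip),
                function(i) paste(node_seq[[i]], collapse = ""), "")
  names(out) <- tree$tip.label
  if (!identical(out, truth$species_seqs[names(out)]))
    stop("internal consistency error: replay does not reproduce species sequences")
  if (!is.null(alignment)) {
    # haplotypes: species sequence + recorded mutations; gaps (later indels)
    # are excluded from the comparison
    for (s in names(out)) {
      nh <- truth$config$n_haplotypes[[s]]
      haps <- replicate(nh, strsplit(out[[s]], "")[[1L]], simplify = FALSE)
      ml <- truth$hap_mutations[[s]]
      for (i in seq_len(nrow(ml %||% data.frame()))) {
        carriers <- as.integer(strsplit(ml$carriers[i], ",")[[1L]])
        for (h in carriers) haps[[h]][ml$column[i] + 1L] <- ml$to[i]
      }
      for (h in seq_len(nh)) {
        emitted <- alignment$mat[paste0(s, "_h", h), ]
        ng <- emitted != "-"
        if (any(emitted[ng] != haps[[h]][ng]))
          stop("internal consistency error: haplotype replay mismatch for ",
               s, "_h", h)
      }
    }
  }
  invisible(out)
}

#' Write a simulated dataset to a directory
#'
#' Emits `alignment.fasta`, `truth.bed`, `tree.nwk` and `truth_events.tsv`
#' (per-branch substitutions, 1-based columns).
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta_alignment(dataset$alignment, file.path(dir, "alignment.fasta"))
  write_interval_track(dataset$truth_track, file.path(dir, "truth.bed"))
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  ev <- do.call(rbind, dataset$truth$branch_events)
  if (is.null(ev)) ev <- data.frame(column = integer(), branch = character(),
                                    from = character(), to = character())
  ev$column <- ev$column + 1L
  utils::write.table(ev, file.path(dir, "truth_events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
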