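#' Configuration for the gene-family simulator
#'
#' Describes a species tree with branch lengths in years (the branch
#' *entering* a labelled node is addressed by that node's label; a root
#' edge, e.g. `"(...)anc:5e6;"`, provides a pre-speciation branch for
#' ancestral duplications), gene duplication/loss events, a TN93
#' substitution process, a micro-indel process, and gene-conversion
#' events. Event times are absolute years from the start of the root edge
#' and must fall strictly inside their branch.
#'
#' @param tree Newick string or `phylo`; branch lengths in years; internal
#'   nodes that carry events must be labelled.
#' @param root_length Root sequence length (columns before insertions).
#' @param regions Optional region map for the root sequence.
#' @param subst List: `rate` (substitutions/site/year), `pi` (A,C,G,T
#'   frequencies), `k1`, `k2` (TN93 transition/transversion rate ratios).
#' @param indel List: `rate` (events/site/year), `mean_len` (geometric mean
#'   length), `max_len` cap.
#' @param duplications Tibble: `species` (branch), `time`, `gene`,
#'   `new_name`, optional `chimeric_with` (second parent gene) and
#'   `breakpoint` (alignment column at event time).
#' @param losses Tibble: `species`, `time`, `gene`.
#' @param conversions Tibble: `species`, `time`, `donor` (`NA` = uniform
#'   among co-resident paralogs), `recipient`, `start` (`NA` = uniform),
#'   `mean_len`, `fixed` (use `mean_len` exactly instead of a geometric
#'   draw).
#' @param root_gene Name of the ancestral gene.
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(tree, root_length = 10000, regions = NULL,
                       subst = list(rate = 1.4e-9, pi = c(0.3, 0.2, 0.2, 0.3),
                                    k1 = 2, k2 = 2),
                       indel = list(rate = 0, mean_len = 4, max_len = 100),
                       duplications = NULL, losses = NULL, conversions = NULL,
                       root_gene = "P1", seed) {
  if (missing(seed)) abort("`seed` is mandatory")
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) abort("`tree` must be newick or phylo")
  stopifnot(subst$rate >= 0, indel$rate >= 0)
  structure(list(tree = tree, root_length = as.integer(root_length),
                 regions = regions, subst = subst, indel = indel,
                 duplications = duplications, losses = losses,
                 conversions = conversions, root_gene = root_gene,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Node times (years from the start of the root edge) and branch lookup.
species_tree_times <- function(tree) {
  root_edge <- tree$root.edge %||% 0
  depth <- ape::node.depth.edgelength(tree) + root_edge
  n_tip <- length(tree$tip.label)
  labels <- c(tree$tip.label,
              tree$node.label %||% rep(NA_character_, tree$Nnode))
  root <- n_tip + 1L
  parent <- rep(NA_integer_, n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  list(depth = depth, labels = labels, root = root, parent = parent,
       root_edge = root_edge, n_tip = n_tip)
}

node_by_label <- function(st, label) {
  hit <- which(st$labels == label)
  if (length(hit) != 1L) abort(sprintf("unknown or ambiguous node label: %s", label))
  hit
}

#' Simulate a gene family with known natural history
#'
#' Forward simulation along the species tree. Substitutions follow the
#' TN93 transition probabilities exactly over each inter-event interval;
#' insertions add columns to the global alignment (all other rows gapped),
#' deletions leave gap columns; duplications clone a gene (or splice a
#' chimeric fusion of two parents); conversions overwrite the recipient's
#' tract with the donor's current sequence. Coordinate bookkeeping uses
#' persistent column identities, so the emitted alignment is the true
#' alignment and every truth record carries final alignment coordinates.
#'
#' @param config A [sim_config()].
#' @return List with `msa` (the true alignment, labels `species_gene`) and
#'   `truth`: `gene_tree` (newick, branch lengths in years),
#'   `conversions`, `indels`, `events` tibbles, and `divergence`
#'   (tibble of true pairwise divergence times in years).
#' @export
simulate_family <- function(config) {
  withr::with_seed(config$seed, simulate_family_impl(config))
}

simulate_family_impl <- function(config) {
  st <- species_tree_times(config$tree)
  model <- tn93_model(config$subst$pi, config$subst$k1, config$subst$k2)

  # --- event queue -----------------------------------------------------
  ev <- list()
  for (v in seq_along(st$depth)) {
    if (v <= st$n_tip) {
      ev[[length(ev) + 1L]] <- tibble(time = st$depth[v], type = "sample",
                                      node = v, payload = list(NULL))
    } else {
      ev[[length(ev) + 1L]] <- tibble(time = st$depth[v], type = "speciation",
                                      node = v, payload = list(NULL))
    }
  }
  add_user_events <- function(tbl, type) {
    if (is.null(tbl) || !nrow(tbl)) return()
    for (i in seq_len(nrow(tbl))) {
      row <- as.list(tbl[i, ])
      v <- node_by_label(st, row$species)
      t0 <- if (v == st$root) st$depth[v] - st$root_edge else st$depth[st$parent[v]]
      if (row$time <= t0 || row$time >= st$depth[v]) {
        abort(sprintf("event time %g outside branch to '%s' (%g, %g)",
                      row$time, row$species, t0, st$depth[v]))
      }
      ev[[length(ev) + 1L]] <<- tibble(time = row$time, type = type, node = v,
                                       payload = list(row))
    }
  }
  add_user_events(config$duplications, "duplication")
  add_user_events(config$losses, "loss")
  add_user_events(config$conversions, "conversion")
  queue <- bind_rows(ev) |> arrange(.data$time)

  # --- state -----------------------------------------------------------
  L0 <- config$root_length
  root_seq <- sample.int(4L, L0, replace = TRUE, prob = config$subst$pi)
  env <- new.env()
  env$col_id <- seq_len(L0)          # persistent column identities
  env$next_col <- L0 + 1L
  env$lineages <- list()             # live lineages
  env$emitted <- list()              # sampled tip rows
  env$spawns <- list()               # (parent, child, time, type)
  env$truth_conv <- list()
  env$truth_indel <- list()
  env$next_lineage <- 1L

  new_lineage <- function(seq, heading, gene, parent = NA_integer_,
                          time = 0, type = "root") {
    id <- env$next_lineage
    env$next_lineage <- id + 1L
    env$lineages[[as.character(id)]] <- list(
      id = id, seq = seq, heading = heading, gene = gene)
    if (!is.na(parent)) {
      env$spawns[[length(env$spawns) + 1L]] <-
        tibble(parent = parent, child = id, time = time, type = type)
    }
    id
  }
  find_lineage <- function(node, gene) {
    for (l in env$lineages) if (l$heading == node && l$gene == gene) return(l$id)
    abort(sprintf("no live gene '%s' on branch to node %d", gene, node))
  }
  lineages_on <- function(node) {
    purrr::keep(env$lineages, ~.x$heading == node)
  }
  splice_columns <- function(pos, n_new) {
    # insert n_new gap columns after alignment position pos (0-based count
    # of columns kept to the left) in every stored sequence
    ins <- function(x, fill) append(x, rep(fill, n_new), after = pos)
    for (k in names(env$lineages)) {
      env$lineages[[k]]$seq <- ins(env$lineages[[k]]$seq, 0L)
    }
    for (k in seq_along(env$emitted)) {
      env$emitted[[k]]$seq <- ins(env$emitted[[k]]$seq, 0L)
    }
    ids <- env$next_col:(env$next_col + n_new - 1L)
    env$next_col <- env$next_col + n_new
    env$col_id <- append(env$col_id, ids, after = pos)
    ids
  }

  evolve_interval <- function(dt, t_end) {
    if (dt <= 0) return()
    d <- config$subst$rate * dt
    if (d > 0) {
      pm <- model$pmat(d)
      cum <- t(apply(pm, 1, cumsum))
      for (k in names(env$lineages)) {
        s <- env$lineages[[k]]$seq
        live_idx <- which(s > 0L)
        if (!length(live_idx)) next
        u <- runif(length(live_idx))
        cur <- s[live_idx]
        new <- integer(length(cur))
        for (state in 1:4) {
          w <- cur == state
          if (any(w)) new[w] <- findInterval(u[w], cum[state, 1:3]) + 1L
        }
        s[live_idx] <- new
        env$lineages[[k]]$seq <- s
      }
    }
    if (config$indel$rate > 0) {
      for (k in names(env$lineages)) apply_indels(k, dt, t_end)
    }
  }

  apply_indels <- function(k, dt, t_end) {
    lin <- env$lineages[[k]]
    n_sites <- sum(lin$seq > 0L)
    n_ev <- rpois(1L, config$indel$rate * n_sites * dt)
    if (!n_ev) return()
    for (e in seq_len(n_ev)) {
      lin <- env$lineages[[k]]
      len <- min(rgeom(1L, 1 / config$indel$mean_len) + 1L, config$indel$max_len)
      if (runif(1) < 0.5) {  # deletion of the lineage's own bases
        alive <- which(lin$seq > 0L)
        if (length(alive) <= len) next
        from <- sample.int(length(alive) - len + 1L, 1L)
        cols <- alive[from:(from + len - 1L)]
        env$lineages[[k]]$seq[cols] <- 0L
        env$truth_indel[[length(env$truth_indel) + 1L]] <- tibble(
          lineage = lin$id, gene = lin$gene, type = "del", time = t_end,
          col_ids = list(env$col_id[cols]), length = len)
      } else {           # insertion: new columns, gaps everywhere else
        alive <- which(lin$seq > 0L)
        pos <- if (length(alive)) sample(c(0L, alive), 1L) else 0L
        ids <- splice_columns(pos, len)
        bases <- sample.int(4L, len, replace = TRUE, prob = config$subst$pi)
        env$lineages[[k]]$seq[(pos + 1L):(pos + len)] <- bases
        env$truth_indel[[length(env$truth_indel) + 1L]] <- tibble(
          lineage = env$lineages[[k]]$id, gene = env$lineages[[k]]$gene,
          type = "ins", time = t_end, col_ids = list(ids), length = len)
      }
    }
  }

  # --- initial lineage -------------------------------------------------
  new_lineage(root_seq, heading = st$root, gene = config$root_gene)

  t_now <- 0
  children_of <- function(v) tree_children(config$tree, v)
  for (i in seq_len(nrow(queue))) {
    evt <- queue[i, ]
    evolve_interval(evt$time - t_now, evt$time)
    t_now <- evt$time
    if (evt$type == "speciation") {
      v <- evt$node
      kids <- children_of(v)
      for (l in lineages_on(v)) {
        for (ci in seq_along(kids)) {
          if (ci == 1L) {
            env$lineages[[as.character(l$id)]]$heading <- kids[ci]
          } else {
            new_lineage(l$seq, heading = kids[ci], gene = l$gene,
                        parent = l$id, time = t_now, type = "speciation")
          }
        }
      }
    } else if (evt$type == "sample") {
      v <- evt$node
      for (l in lineages_on(v)) {
        env$emitted[[length(env$emitted) + 1L]] <- list(
          label = paste(st$labels[v], l$gene, sep = "_"),
          species = st$labels[v], gene = l$gene, lineage = l$id,
          seq = l$seq, time = t_now)
        env$lineages[[as.character(l$id)]] <- NULL
      }
    } else if (evt$type == "duplication") {
      p <- evt$payload[[1L]]
      src <- find_lineage(evt$node, p$gene)
      seq <- env$lineages[[as.character(src)]]$seq
      chim <- p$chimeric_with %||% NA
      if (!is.na(chim)) {
        other <- find_lineage(evt$node, chim)
        bp <- p$breakpoint
        oseq <- env$lineages[[as.character(other)]]$seq
        seq <- c(seq[seq_len(bp)], oseq[(bp + 1L):length(oseq)])
      }
      new_lineage(seq, heading = evt$node, gene = p$new_name, parent = src,
                  time = t_now, type = "duplication")
    } else if (evt$type == "loss") {
      p <- evt$payload[[1L]]
      id <- find_lineage(evt$node, p$gene)
      env$lineages[[as.character(id)]] <- NULL
    } else if (evt$type == "conversion") {
      p <- evt$payload[[1L]]
      rec <- find_lineage(evt$node, p$recipient)
      donor_gene <- p$donor %||% NA
      if (is.na(donor_gene)) {
        cand <- setdiff(purrr::map_chr(lineages_on(evt$node), "gene"), p$recipient)
        donor_gene <- sample(cand, 1L)
      }
      don <- find_lineage(evt$node, donor_gene)
      L <- length(env$col_id)
      len <- if (isTRUE(p$fixed)) as.integer(p$mean_len) else
        min(rgeom(1L, 1 / p$mean_len) + 1L, L)
      start <- p$start %||% NA
      if (is.na(start)) start <- sample.int(L - len + 1L, 1L) - 1L
      cols <- (start + 1L):(start + len)
      dseq <- env$lineages[[as.character(don)]]$seq
      rseq <- env$lineages[[as.character(rec)]]$seq
      n_diff <- sum(dseq[cols] != rseq[cols] &
                      dseq[cols] > 0L & rseq[cols] > 0L)
      env$lineages[[as.character(rec)]]$seq[cols] <- dseq[cols]
      env$truth_conv[[length(env$truth_conv) + 1L]] <- tibble(
        time = t_now, species = st$labels[evt$node], donor = donor_gene,
        recipient = p$recipient, col_ids = list(env$col_id[cols]),
        length = len, n_diff_before = n_diff)
    }
  }

  # --- assemble outputs ------------------------------------------------
  final_pos <- setNames(seq_along(env$col_id) - 1L, env$col_id)  # 0-based
  labels <- purrr::map_chr(env$emitted, "label")
  mat <- do.call(rbind, purrr::map(env$emitted, function(e) {
    c("-", NT_LEVELS)[e$seq + 1L]
  }))
  rownames(mat) <- labels
  species <- setNames(purrr::map_chr(env$emitted, "species"), labels)
  out_msa <- msa(mat, species = species)
  if (!is.null(config$regions)) {
    # region map applies to root coordinates; translate via column ids
    regs <- purrr::pmap(config$regions, function(region, start, end, frame = NA) {
      ids <- (start + 1L):end  # root columns have ids 1..L0
      pos <- final_pos[as.character(ids)]
      tibble(region = region, start = min(pos), end = max(pos) + 1L,
             frame = as.integer(frame))
    }) |> bind_rows()
    # extend region ends so inserted columns between regions are covered
    regs <- arrange(regs, .data$start)
    if (nrow(regs) > 1L) regs$end[-nrow(regs)] <- regs$start[-1L]
    regs$end[nrow(regs)] <- msa_width(out_msa)
    regs$start[1L] <- 0L
    out_msa$regions <- validate_regions(regs, msa_width(out_msa))
  }

  to_coords <- function(ids) {
    pos <- final_pos[as.character(ids)]
    tibble(start = min(pos), end = max(pos) + 1L, n_cols = length(pos))
  }
  conv <- purrr::map(env$truth_conv, function(tc) {
    dplyr::bind_cols(tc[setdiff(names(tc), "col_ids")], to_coords(tc$col_ids[[1L]]))
  }) |> bind_rows()
  indels <- purrr::map(env$truth_indel, function(ti) {
    dplyr::bind_cols(ti[setdiff(names(ti), "col_ids")], to_coords(ti$col_ids[[1L]]))
  }) |> bind_rows()

  spawns <- if (length(env$spawns)) bind_rows(env$spawns) else
    tibble(parent = integer(), child = integer(), time = double(),
           type = character())
  tips <- tibble(lineage = purrr::map_int(env$emitted, "lineage"),
                 label = labels,
                 time = purrr::map_dbl(env$emitted, "time"))
  gene_tree <- build_gene_tree(spawns, tips)
  divergence <- true_divergence(spawns, tips)

  list(msa = out_msa,
       truth = list(gene_tree = gene_tree, conversions = conv,
                    indels = indels, spawns = spawns, tips = tips,
                    divergence = divergence))
}

tree_children <- function(tree, v) tree$edge[tree$edge[, 1] == v, 2]

# Newick gene tree from spawn records; lineages without surviving tips are
# pruned. Branch lengths in years.
build_gene_tree <- function(spawns, tips) {
  tip_of <- setNames(tips$label, tips$lineage)
  tip_time <- setNames(tips$time, tips$lineage)
  kids_of <- split(seq_len(nrow(spawns)), spawns$parent)
  # fold the k-th and later spawn events of lineage `id` into nested nodes
  newick <- function(id, t0, k = 1L) {
    sp <- spawns[unlist(kids_of[[as.character(id)]]), , drop = FALSE]
    sp <- sp[order(sp$time), , drop = FALSE]
    if (k > nrow(sp)) {
      if (!as.character(id) %in% names(tip_of)) return(NULL)
      return(sprintf("%s:%.9g", tip_of[[as.character(id)]],
                     tip_time[[as.character(id)]] - t0))
    }
    t1 <- sp$time[k]
    left <- newick(id, t1, k + 1L)
    right <- newick(sp$child[k], t1)
    if (is.null(left) && is.null(right)) return(NULL)
    if (is.null(left)) {
      # continuing lineage died out: child subtree extends through this point
      return(add_length(right, t1 - t0))
    }
    if (is.null(right)) return(add_length(left, t1 - t0))
    sprintf("(%s,%s)%s:%.9g", left, right, sp$type[k], t1 - t0)
  }
  txt <- newick(1L, 0)
  if (is.null(txt)) return(NULL)
  paste0(sub(":[0-9.eE+-]+$", "", txt), ";")
}

add_length <- function(newick_frag, extra) {
  m <- regmatches(newick_frag, regexpr(":[0-9.eE+-]+$", newick_frag))
  old <- as.numeric(sub(":", "", m))
  sub(":[0-9.eE+-]+$", sprintf(":%.9g", old + extra), newick_frag)
}

# True pairwise divergence times from the lineage ancestry.
true_divergence <- function(spawns, tips) {
  parent_of <- setNames(spawns$parent, spawns$child)
  time_of <- setNames(spawns$time, spawns$child)
  path <- function(id) {
    ids <- id
    while (as.character(id) %in% names(parent_of)) {
      id <- parent_of[[as.character(id)]]
      ids <- c(id, ids)
    }
    ids
  }
  leave_time <- function(p, x) {
    # time at which path p leaves lineage x (Inf if it ends on x)
    i <- match(x, p)
    if (i == length(p)) return(Inf)
    time_of[[as.character(p[i + 1L])]]
  }
  out <- list()
  n <- nrow(tips)
  paths <- purrr::map(tips$lineage, path)
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      common <- intersect(paths[[i]], paths[[j]])
      x <- common[length(common)]
      tdiv <- min(leave_time(paths[[i]], x), leave_time(paths[[j]], x))
      out[[length(out) + 1L]] <- tibble(
        label_a = tips$label[i], label_b = tips$label[j],
        t_divergence = tdiv)
    }
  }
  bind_rows(out)
}
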