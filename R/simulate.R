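# Synthetic two-tissue study generator.
#
# One shared gene universe carries a planted block partition. Each tissue
# "owns" a subset of the blocks: in that tissue's expression matrix the owned
# blocks behave as co-expression modules (a shared per-module latent factor),
# while the other tissue's blocks are plain background genes. The PPI graph
# is a planted partition over all blocks, so every tissue's modules are
# assortative on the graph, and designated cross-tissue block pairs receive
# extra inter-block edges (planted crosstalk).

#' Build a simulation configuration
#'
#' Defaults describe the reference two-tissue study design: a corpus-callosum
#' style cohort of 12 cases vs 12 controls and a prefrontal-cortex style
#' cohort of 13 cases vs 39 controls over one shared 900-gene universe with
#' ten planted 60-gene blocks (five owned by each tissue).
#'
#' @param n_genes number of genes in the universe.
#' @param module_sizes integer vector of planted block sizes (blocks occupy
#'   consecutive genes starting at gene 1; remaining genes are background).
#' @param tissues character vector of tissue names.
#' @param tissue_modules named list (per tissue) of block indices owned by
#'   that tissue; owned blocks are that tissue's co-expression modules.
#' @param n_case,n_control named integer vectors of per-tissue sample counts.
#' @param module_loading loading `lambda` in `[0,1]` of the shared per-module
#'   latent factor on the log mean.
#' @param de_log2fc planted absolute log2 fold change of DE genes (sign
#'   random per gene).
#' @param de_fraction fraction of genes planted as differentially expressed
#'   per tissue.
#' @param nb_dispersion negative-binomial dispersion `alpha`
#'   (Var = mu + alpha * mu^2), one global value.
#' @param intra_edge_p,inter_edge_p within-/between-block edge probabilities
#'   of the planted-partition PPI graph (`intra_edge_p > inter_edge_p`).
#' @param decoy_fraction fraction (of the high-confidence edge count) of
#'   additional low-confidence decoy edges with combined scores in
#'   `[150, 899]`, exercising the score filter.
#' @param regulator_counts named integer vector `c(TF=, miRNA=, lncRNA=)`.
#' @param targets_per_regulator target-set size per regulator.
#' @param n_pivots named integer vector of planted pivot regulators per type.
#' @param targeting_odds odds with which a planted pivot samples targets from
#'   its module vs background (1 = no planted pivots).
#' @param risk_odds odds with which risk lists sample genes from their
#'   designated modules vs background (1 = uniform list).
#' @param risk_list_size named vector `c(sfari=, dvmt=)` of risk-list sizes.
#' @param risk_modules named list of block indices the two risk lists are
#'   enriched in.
#' @param tissue_list_size size of the tissue-specific gene list.
#' @param tissue_specific_modules named list (per tissue) of owned blocks
#'   that the tissue-specific list is seeded into (these become the
#'   tissue-specific crosstalk candidates).
#' @param crosstalk_pairs list of length-2 integer vectors `(block A, block
#'   B)` given extra inter-block PPI edges.
#' @param crosstalk_boost multiple of the expected background inter-block
#'   edge count that planted crosstalk pairs are raised to (at least).
#' @param seed integer root seed; all stages derive named substreams from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 900L,
                       module_sizes = rep(60L, 10L),
                       tissues = c("CC", "PFC"),
                       tissue_modules = list(CC = 1:5, PFC = 6:10),
                       n_case = c(CC = 12L, PFC = 13L),
                       n_control = c(CC = 12L, PFC = 39L),
                       module_loading = 0.75,
                       de_log2fc = 1,
                       de_fraction = 0.1,
                       nb_dispersion = 0.15,
                       intra_edge_p = 0.3,
                       inter_edge_p = 0.01,
                       decoy_fraction = 0.2,
                       regulator_counts = c(TF = 10L, miRNA = 15L, lncRNA = 5L),
                       targets_per_regulator = 50L,
                       n_pivots = c(TF = 2L, miRNA = 2L, lncRNA = 1L),
                       targeting_odds = 20,
                       risk_odds = 10,
                       risk_list_size = c(sfari = 60L, dvmt = 60L),
                       risk_modules = list(sfari = c(1L, 6L), dvmt = c(2L, 7L)),
                       tissue_list_size = 120L,
                       tissue_specific_modules = list(CC = 1:3, PFC = 6:8),
                       crosstalk_pairs = list(c(1L, 6L)),
                       crosstalk_boost = 5,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), module_sizes = as.integer(module_sizes),
    tissues = tissues, tissue_modules = tissue_modules,
    n_case = n_case, n_control = n_control,
    module_loading = module_loading, de_log2fc = de_log2fc,
    de_fraction = de_fraction, nb_dispersion = nb_dispersion,
    intra_edge_p = intra_edge_p, inter_edge_p = inter_edge_p,
    decoy_fraction = decoy_fraction, regulator_counts = regulator_counts,
    targets_per_regulator = as.integer(targets_per_regulator),
    n_pivots = n_pivots, targeting_odds = targeting_odds,
    risk_odds = risk_odds, risk_list_size = risk_list_size,
    risk_modules = risk_modules, tissue_list_size = as.integer(tissue_list_size),
    tissue_specific_modules = tissue_specific_modules,
    crosstalk_pairs = crosstalk_pairs, crosstalk_boost = crosstalk_boost,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#' @param config a `sim_config` list.
#' @return The config, invisibly; errors on violation.
#' @export
validate_sim_config <- function(config) {
  with(config, {
    stopifnot(n_genes >= 1L, all(module_sizes >= 1L) || length(module_sizes) == 0L)
    if (sum(module_sizes) > n_genes) {
      stop("sum(module_sizes) = ", sum(module_sizes),
           " exceeds n_genes = ", n_genes)
    }
    if (!(intra_edge_p > 0 && intra_edge_p <= 1)) {
      stop("intra_edge_p must be in (0, 1]")
    }
    if (!(inter_edge_p >= 0 && inter_edge_p < 1)) {
      stop("inter_edge_p must be in [0, 1)")
    }
    if (intra_edge_p <= inter_edge_p) {
      stop("planted partition must be assortative: intra_edge_p > inter_edge_p")
    }
    stopifnot(module_loading >= 0, module_loading <= 1,
              de_log2fc >= 0, de_fraction > 0, de_fraction < 1,
              nb_dispersion > 0, targeting_odds >= 1, risk_odds >= 1,
              decoy_fraction >= 0, crosstalk_boost >= 1)
    stopifnot(all(tissues %in% names(tissue_modules)),
              all(tissues %in% names(n_case)),
              all(tissues %in% names(n_control)),
              all(n_case[tissues] >= 1L), all(n_control[tissues] >= 1L))
    owned <- unlist(tissue_modules[tissues], use.names = FALSE)
    if (length(owned) && any(!owned %in% seq_along(module_sizes))) {
      stop("tissue_modules refers to a block index outside module_sizes")
    }
    for (p in crosstalk_pairs) {
      if (length(p) != 2L || any(!p %in% seq_along(module_sizes))) {
        stop("each crosstalk pair must be two valid block indices")
      }
    }
  })
  invisible(config)
}

gene_ids <- function(n) sprintf("G%04d", seq_len(n))

# Block membership over the whole universe: integer labels, 0 = background.
planted_blocks <- function(config) {
  lab <- integer(config$n_genes)
  pos <- 1L
  for (m in seq_along(config$module_sizes)) {
    sz <- config$module_sizes[m]
    lab[pos:(pos + sz - 1L)] <- m
    pos <- pos + sz
  }
  names(lab) <- gene_ids(config$n_genes)
  lab
}

#' Plant the ground truth of a synthetic study
#'
#' Fixes everything the downstream recovery tests score against: block
#' membership, per-tissue planted DE genes (with their signs), planted pivot
#' regulators and their modules, and the designated crosstalk block pairs.
#' Risk and tissue-specific gene lists are filled in by
#' [simulate_gene_lists()].
#'
#' Every module owned by a tissue is guaranteed at least eight planted DE
#' genes in that tissue, so all planted modules are exercised by the
#' downstream candidate-module selection even when the DE screen misses a
#' fraction of the planted genes.
#'
#' @param config a [sim_config()].
#' @return A list of class `synthetic_truth`.
#' @export
plant_truth <- function(config) {
  validate_sim_config(config)
  genes <- gene_ids(config$n_genes)
  blocks <- planted_blocks(config)

  de_genes <- list(); de_sign <- list(); de_forced <- list()
  for (ts in config$tissues) {
    sd_seed <- substream_seed(config$seed, "truth", "de", ts)
    de <- with_seed(sd_seed, {
      base <- sample(genes, max(1L, round(config$de_fraction * config$n_genes)))
      forced <- unlist(lapply(config$tissue_modules[[ts]], function(m) {
        sample(genes[blocks == m], min(8L, sum(blocks == m)))
      }))
      list(de = sort(unique(c(base, forced))), forced = forced)
    })
    forced <- de$forced
    de <- de$de
    sgn <- with_seed(substream_seed(config$seed, "truth", "de_sign", ts), {
      s <- sample(c(-1, 1), length(de), replace = TRUE)
      names(s) <- de
      # balanced signs among each module's guarantee genes: the module's
      # shared latent factor shifts all members' observed fold changes in
      # one direction, so same-signed guarantees would fail together
      s[forced] <- rep_len(c(-1, 1), length(forced))
      s
    })
    de_genes[[ts]] <- de
    de_sign[[ts]] <- sgn
    de_forced[[ts]] <- forced
  }

  pivots <- data.frame(regulator = character(), type = character(),
                       module = integer())
  if (config$targeting_odds > 1) {
    host_modules <- unlist(config$tissue_specific_modules[config$tissues],
                           use.names = FALSE)
    if (!length(host_modules)) {
      host_modules <- unlist(config$tissue_modules[config$tissues],
                             use.names = FALSE)
    }
    k <- 0L
    for (ty in names(config$n_pivots)) {
      np <- config$n_pivots[[ty]]
      if (np < 1L) next
      if (np > config$regulator_counts[[ty]]) {
        stop("more planted pivots than regulators of type ", ty)
      }
      for (i in seq_len(np)) {
        k <- k + 1L
        m <- host_modules[(k - 1L) %% length(host_modules) + 1L]
        if (sum(blocks == m) < 2L) {
          stop("planted pivot module ", m, " has fewer than 2 genes")
        }
        pivots <- rbind(pivots, data.frame(
          regulator = regulator_id(ty, i), type = ty, module = m))
      }
    }
  }

  truth <- list(
    genes = genes,
    module_membership = blocks,
    de_genes = de_genes,
    de_sign = de_sign,
    de_forced = de_forced,
    pivot_regulators = pivots,
    risk_genes = NULL,
    tissue_specific_genes = NULL,
    crosstalk_pairs = config$crosstalk_pairs)
  class(truth) <- "synthetic_truth"
  truth
}

regulator_id <- function(type, i) {
  prefix <- c(TF = "TF", miRNA = "MIR", lncRNA = "LNC")[[type]]
  sprintf("%s%03d", prefix, i)
}

#' Planted module labels restricted to one tissue
#'
#' Blocks not owned by the tissue are background (label 0) in that tissue's
#' expression data; this is the reference partition that module-recovery
#' metrics compare against.
#'
#' @param truth a `synthetic_truth`.
#' @param config the generating [sim_config()].
#' @param tissue tissue name.
#' @return Named integer vector over all genes (0 = background).
#' @export
planted_membership <- function(truth, config, tissue) {
  lab <- truth$module_membership
  lab[!(lab %in% config$tissue_modules[[tissue]])] <- 0L
  lab
}

#' Generate the planted-partition PPI network
#'
#' Gene pairs within a planted block are connected with probability
#' `intra_edge_p`, all other pairs with `inter_edge_p`. High-confidence edges
#' carry integer combined scores drawn uniformly from `[900, 1000]`; a
#' configurable fraction of decoy edges with scores in `[150, 899]` is added
#' so the score filter is exercised. Designated crosstalk block pairs are
#' topped up with extra inter-block edges until they hold at least
#' `crosstalk_boost` times the expected background inter-block count.
#'
#' @param config a [sim_config()].
#' @param truth optional pre-planted truth (defaults to [plant_truth()]).
#' @return List with elements `network` (igraph with `combined_score` edge
#'   attribute; all genes present as vertices) and `truth`.
#' @export
simulate_ppi_network <- function(config, truth = plant_truth(config)) {
  validate_sim_config(config)
  genes <- truth$genes
  blocks <- truth$module_membership
  n <- config$n_genes

  edges <- with_seed(substream_seed(config$seed, "network"), {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- pairs[, 1]; j <- pairs[, 2]
    same <- blocks[i] != 0L & blocks[i] == blocks[j]
    p <- ifelse(same, config$intra_edge_p, config$inter_edge_p)
    keep <- runif(length(p)) < p
    ei <- i[keep]; ej <- j[keep]
    score <- sample(900:1000, sum(keep), replace = TRUE)

    # planted crosstalk: top up inter-block edges for designated pairs
    for (pr in config$crosstalk_pairs) {
      a <- which(blocks == pr[1]); b <- which(blocks == pr[2])
      target <- ceiling(config$crosstalk_boost * config$inter_edge_p *
                          length(a) * length(b))
      cross <- (blocks[ei] == pr[1] & blocks[ej] == pr[2]) |
               (blocks[ei] == pr[2] & blocks[ej] == pr[1])
      deficit <- target - sum(cross)
      if (deficit > 0) {
        cand <- expand.grid(i = a, j = b)
        key_have <- paste(pmin(ei, ej), pmax(ei, ej))
        cand_key <- paste(pmin(cand$i, cand$j), pmax(cand$i, cand$j))
        cand <- cand[!(cand_key %in% key_have), , drop = FALSE]
        add <- cand[sample.int(nrow(cand), min(deficit, nrow(cand))), ]
        ei <- c(ei, add$i); ej <- c(ej, add$j)
        score <- c(score, sample(900:1000, nrow(add), replace = TRUE))
      }
    }

    # low-confidence decoys among remaining non-edges
    n_decoy <- round(config$decoy_fraction * length(ei))
    if (n_decoy > 0) {
      key_have <- paste(pmin(ei, ej), pmax(ei, ej))
      di <- integer(0); dj <- integer(0)
      while (length(di) < n_decoy) {
        ci <- sample.int(n, 2L * n_decoy, replace = TRUE)
        cj <- sample.int(n, 2L * n_decoy, replace = TRUE)
        ok <- ci != cj
        ci <- ci[ok]; cj <- cj[ok]
        key <- paste(pmin(ci, cj), pmax(ci, cj))
        ok <- !(key %in% key_have) & !duplicated(key)
        di <- c(di, ci[ok]); dj <- c(dj, cj[ok])
        key_have <- c(key_have, key[ok])
        dup <- duplicated(paste(pmin(di, dj), pmax(di, dj)))
        di <- di[!dup]; dj <- dj[!dup]
      }
      di <- di[seq_len(n_decoy)]; dj <- dj[seq_len(n_decoy)]
      ei <- c(ei, di); ej <- c(ej, dj)
      score <- c(score, sample(150:899, n_decoy, replace = TRUE))
    }

    data.frame(protein1 = genes[ei], protein2 = genes[ej],
               combined_score = as.integer(score))
  })

  net <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = genes))
  list(network = net, truth = truth, edges = edges)
}

#' Generate one tissue's NB count matrix with planted structure
#'
#' Counts follow `NB(mean = s_j * exp(b_i + lambda * f[m(i), j] +
#' beta_i * case_j), Var = mu + alpha * mu^2)` with gene baselines
#' `b_i ~ N(log 100, 1)`, sample depth factors `s_j ~ LogNormal(0, 0.2)`, a
#' per-module per-sample standard-normal latent factor `f` shared by module
#' members (only for blocks owned by the tissue), and
#' `beta_i = +/- de_log2fc * log(2)` for the tissue's planted DE genes.
#'
#' @param truth a `synthetic_truth`.
#' @param config the generating [sim_config()].
#' @param tissue tissue name (must appear in `config$tissues`).
#' @return List with `counts` (integer gene-by-sample matrix) and `samples`
#'   (data.frame `sample_id`, `condition`, `tissue`).
#' @export
simulate_expression <- function(truth, config, tissue) {
  validate_sim_config(config)
  stopifnot(tissue %in% config$tissues)
  n_case <- config$n_case[[tissue]]; n_ctrl <- config$n_control[[tissue]]
  if (n_case < 1L || n_ctrl < 1L) stop("empty sample group for ", tissue)
  genes <- truth$genes
  if (!all(names(truth$module_membership) == genes)) {
    stop("truth membership does not cover the gene universe")
  }
  n_s <- n_case + n_ctrl
  samples <- data.frame(
    sample_id = c(sprintf("%s_case_%02d", tissue, seq_len(n_case)),
                  sprintf("%s_ctrl_%02d", tissue, seq_len(n_ctrl))),
    condition = rep(c("case", "control"), c(n_case, n_ctrl)),
    tissue = tissue)

  counts <- with_seed(substream_seed(config$seed, "expression", tissue), {
    lab <- planted_membership(truth, config, tissue)
    b <- rnorm(length(genes), log(100), 1)
    s <- rlnorm(n_s, 0, 0.2)
    owned <- config$tissue_modules[[tissue]]
    f <- matrix(rnorm(length(owned) * n_s), nrow = length(owned),
                dimnames = list(as.character(owned), NULL))
    beta <- numeric(length(genes)); names(beta) <- genes
    de <- truth$de_genes[[tissue]]
    beta[de] <- truth$de_sign[[tissue]][de] * config$de_log2fc * log(2)
    case <- as.numeric(samples$condition == "case")

    eta <- matrix(b, length(genes), n_s) + outer(beta, case)
    in_mod <- lab != 0L
    if (any(in_mod) && config$module_loading > 0) {
      eta[in_mod, ] <- eta[in_mod, ] +
        config$module_loading * f[as.character(lab[in_mod]), , drop = FALSE]
    }
    mu <- sweep(exp(eta), 2, s, `*`)
    if (!all(is.finite(mu)) || max(mu) > 1e12) {
      stop("negative-binomial mean overflow; check config magnitudes")
    }
    m <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                nrow = length(genes),
                dimnames = list(genes, samples$sample_id))
    storage.mode(m) <- "integer"
    m
  })
  list(counts = counts, samples = samples)
}

#' Generate regulator-target maps with planted pivots
#'
#' Each regulator receives a fixed-size target set sampled without
#' replacement from the gene universe; planted pivots weight genes of their
#' module by `targeting_odds` and are guaranteed at least two in-module
#' targets.
#'
#' @param truth a `synthetic_truth`.
#' @param config the generating [sim_config()].
#' @return Named list of target-gene vectors with a `description` attribute
#'   carrying the regulator type (same shape as [read_gmt()] output).
#' @export
simulate_regulators <- function(truth, config) {
  validate_sim_config(config)
  genes <- truth$genes
  blocks <- truth$module_membership
  nt <- config$targets_per_regulator
  if (nt > length(genes)) stop("targets_per_regulator exceeds gene universe")
  pivots <- truth$pivot_regulators

  with_seed(substream_seed(config$seed, "regulators"), {
    sets <- list(); desc <- character()
    for (ty in names(config$regulator_counts)) {
      for (i in seq_len(config$regulator_counts[[ty]])) {
        rid <- regulator_id(ty, i)
        hit <- pivots$module[pivots$regulator == rid]
        w <- rep(1, length(genes))
        if (length(hit) == 1L) {
          if (sum(blocks == hit) < 2L) {
            stop("pivot module ", hit, " smaller than 2 genes")
          }
          w[blocks == hit] <- config$targeting_odds
        }
        tg <- sample(genes, nt, prob = w)
        if (length(hit) == 1L && sum(blocks[tg] == hit) < 2L) {
          pool <- setdiff(genes[blocks == hit], tg)
          need <- 2L - sum(blocks[tg] == hit)
          swap_in <- sample(pool, need)
          out_pool <- which(blocks[tg] != hit)
          tg[out_pool[sample.int(length(out_pool), need)]] <- swap_in
        }
        sets[[rid]] <- tg
        desc[[rid]] <- ty
      }
    }
    attr(sets, "description") <- desc
    sets
  })
}

#' Generate risk-gene lists and the tissue-specific gene list
#'
#' Risk lists (SFARI-like and DVMT-like) sample genes with odds `risk_odds`
#' from their designated blocks versus background. The tissue-specific list
#' samples genes with the same odds from the designated tissue-specific
#' blocks and force-includes, per designated block, eight of the owning
#' tissue's planted DE genes, so designated blocks qualify as
#' tissue-specific modules downstream.
#'
#' @param truth a `synthetic_truth`.
#' @param config the generating [sim_config()].
#' @return List with `sfari`, `dvmt`, `tissue_specific` character vectors.
#' @export
simulate_gene_lists <- function(truth, config) {
  validate_sim_config(config)
  genes <- truth$genes
  blocks <- truth$module_membership

  weighted_list <- function(target_blocks, size, odds) {
    w <- rep(1, length(genes))
    if (length(target_blocks)) w[blocks %in% target_blocks] <- odds
    sample(genes, size, prob = w)
  }

  with_seed(substream_seed(config$seed, "lists"), {
    sfari <- weighted_list(config$risk_modules$sfari,
                           config$risk_list_size[["sfari"]], config$risk_odds)
    dvmt <- weighted_list(config$risk_modules$dvmt,
                          config$risk_list_size[["dvmt"]], config$risk_odds)
    designated <- unlist(config$tissue_specific_modules[config$tissues],
                         use.names = FALSE)
    if (length(designated)) {
      # genes differential between the two tissues concentrate in the
      # designated blocks and the unstructured background; blocks shared
      # between conditions but not designated never enter the list
      w <- rep(1, length(genes))
      w[blocks %in% designated] <- config$risk_odds
      w[blocks != 0L & !(blocks %in% designated)] <- 0
      tiss <- sample(genes, config$tissue_list_size, prob = w)
    } else {
      tiss <- sample(genes, config$tissue_list_size)
    }
    for (ts in config$tissues) {
      for (m in config$tissue_specific_modules[[ts]]) {
        # the balanced-sign guarantee genes of the block, so the listed DE
        # genes cannot all be pushed below the screen's threshold by one
        # draw of the module's shared latent factor
        pool <- intersect(truth$de_forced[[ts]], genes[blocks == m])
        if (!length(pool)) {
          pool <- intersect(genes[blocks == m], truth$de_genes[[ts]])
        }
        if (length(pool)) {
          tiss <- union(tiss, pool[seq_len(min(8L, length(pool)))])
        }
      }
    }
    list(sfari = sort(unique(sfari)), dvmt = sort(unique(dvmt)),
         tissue_specific = sort(unique(tiss)))
  })
}

#' Generate a complete synthetic study
#'
#' Runs all generators under one root seed and optionally writes every input
#' file of the pipeline (counts and metadata per tissue, edge list, gene
#' lists, regulator GMT, truth tables) to a directory.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; created if missing.
#' @return List with `config`, `truth` (lists filled in), `network`, `edges`,
#'   `expression` (per-tissue list of `counts` + `samples`), `regulators`,
#'   `lists`, and (if `dir` given) `paths`.
#' @export
simulate_study <- function(config = sim_config(), dir = NULL) {
  validate_sim_config(config)
  net <- simulate_ppi_network(config)
  truth <- net$truth
  expression <- lapply(stats::setNames(config$tissues, config$tissues),
                       function(ts) simulate_expression(truth, config, ts))
  regulators <- simulate_regulators(truth, config)
  lists <- simulate_gene_lists(truth, config)
  truth$risk_genes <- lists[c("sfari", "dvmt")]
  truth$tissue_specific_genes <- lists$tissue_specific

  out <- list(config = config, truth = truth, network = net$network,
              edges = net$edges, expression = expression,
              regulators = regulators, lists = lists)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list()
    for (ts in config$tissues) {
      paths[[paste0("counts_", ts)]] <- file.path(dir, paste0("counts_", ts, ".tsv"))
      write_counts(expression[[ts]]$counts, paths[[paste0("counts_", ts)]])
      paths[[paste0("metadata_", ts)]] <- file.path(dir, paste0("metadata_", ts, ".tsv"))
      write_tsv(expression[[ts]]$samples, paths[[paste0("metadata_", ts)]])
    }
    paths$network <- file.path(dir, "network.tsv")
    write_tsv(net$edges, paths$network)
    paths$sfari <- file.path(dir, "sfari.txt")
    write_gene_list(lists$sfari, paths$sfari)
    paths$dvmt <- file.path(dir, "dvmt.txt")
    write_gene_list(lists$dvmt, paths$dvmt)
    paths$tissue_genes <- file.path(dir, "tissue_genes.txt")
    write_gene_list(lists$tissue_specific, paths$tissue_genes)
    paths$regulators <- file.path(dir, "regulators.gmt")
    write_gmt(regulators, paths$regulators,
              descriptions = attr(regulators, "description"))
    paths$truth_modules <- file.path(dir, "truth_modules.tsv")
    write_tsv(data.frame(gene_id = truth$genes,
                         block = unname(truth$module_membership)),
              paths$truth_modules)
    for (ts in config$tissues) {
      paths[[paste0("truth_de_", ts)]] <- file.path(dir, paste0("truth_de_", ts, ".tsv"))
      write_tsv(data.frame(gene_id = truth$de_genes[[ts]],
                           sign = unname(truth$de_sign[[ts]][truth$de_genes[[ts]]])),
                paths[[paste0("truth_de_", ts)]])
    }
    paths$truth_pivots <- file.path(dir, "truth_pivots.tsv")
    write_tsv(truth$pivot_regulators, paths$truth_pivots)
    out$paths <- paths
  }
  out
}

#' Simulate a plain two-group NB count matrix (no co-expression structure)
#'
#' Convenience wrapper for differential-expression calibration experiments:
#' independent NB genes, a fixed number planted with `+/- log2fc`, no latent
#' module factor.
#'
#' @param n_genes,n_case,n_control problem size.
#' @param n_de number of planted DE genes (the first `n_de` genes).
#' @param log2fc planted absolute log2 fold change.
#' @param dispersion NB dispersion.
#' @param seed root seed.
#' @return List with `counts`, `samples`, `de_genes`.
#' @export
simulate_de_counts <- function(n_genes = 2000L, n_case = 12L, n_control = 12L,
                               n_de = 0L, log2fc = 1, dispersion = 0.2,
                               seed = 1L) {
  stopifnot(n_de <= n_genes)
  cfg <- sim_config(
    n_genes = n_genes, module_sizes = integer(0),
    tissues = "T", tissue_modules = list(T = integer(0)),
    n_case = c(T = n_case), n_control = c(T = n_control),
    module_loading = 0, de_log2fc = log2fc,
    de_fraction = 1e-9, nb_dispersion = dispersion,
    regulator_counts = c(TF = 1L, miRNA = 1L, lncRNA = 1L),
    n_pivots = c(TF = 0L, miRNA = 0L, lncRNA = 0L),
    risk_modules = list(sfari = integer(0), dvmt = integer(0)),
    tissue_specific_modules = list(T = integer(0)),
    crosstalk_pairs = list(), seed = seed)
  truth <- plant_truth(cfg)
  truth$de_genes$T <- gene_ids(n_genes)[seq_len(n_de)]
  truth$de_sign$T <- with_seed(substream_seed(seed, "de_counts", "sign"), {
    s <- sample(c(-1, 1), n_de, replace = TRUE)
    names(s) <- truth$de_genes$T
    s
  })
  sim <- simulate_expression(truth, cfg, "T")
  list(counts = sim$counts, samples = sim$samples, de_genes = truth$de_genes$T)
}
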