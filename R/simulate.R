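#' Simulation configuration for toy gene families
#'
#' Defines the generative model: an ancestral gene (exon-intron structure and
#' a set of alternative transcripts built as exon subsets) evolves along a
#' rooted tree; along each branch every site substitutes at \code{sub_rate}
#' per branch-length unit and every transcript may undergo one exon-skipping
#' event at rate \code{skip_prob} per branch-length unit (which moves its
#' descendants into a new splicing-ortholog group). Exons mutate by
#' substitution only, so gene coordinates are conserved and the true
#' alignment is exact per column.
#'
#' @param tree Newick string, rooted, with branch lengths.
#' @param exon_count Integer range (min, max) of ancestral exons.
#' @param exon_len Range of exon lengths in nucleotides; draws are multiples
#'   of 3 so that segment lengths stay frame-compatible.
#' @param intron_len Range of intron (and flank) lengths.
#' @param sub_rate Substitutions per site per branch-length unit.
#' @param transcripts Integer range of ancestral transcripts per gene.
#' @param skip_prob Exon-skipping events per transcript per branch-length unit.
#' @param seed Integer seed; identical seeds give identical families.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(tree = "(((A:1,B:1):1,C:2):1,(D:2,E:2):1);",
                       exon_count = c(4L, 8L), exon_len = c(12L, 60L),
                       intron_len = c(20L, 60L), sub_rate = 0.05,
                       transcripts = c(1L, 3L), skip_prob = 0.1, seed = 1L) {
  stopifnot(exon_count[1] >= 1L, exon_len[1] >= 3L, intron_len[1] >= 1L,
            sub_rate >= 0, skip_prob >= 0, transcripts[1] >= 1L)
  structure(list(tree = tree, exon_count = as.integer(exon_count),
                 exon_len = as.integer(exon_len),
                 intron_len = as.integer(intron_len), sub_rate = sub_rate,
                 transcripts = as.integer(transcripts),
                 skip_prob = skip_prob, seed = as.integer(seed)),
            class = "sim_config")
}

rand_range <- function(r) if (r[1] >= r[2]) r[1] else sample(r[1]:r[2], 1L)

#' Simulate a gene family with known truth
#'
#' Generates leaf gene models plus the ground truth needed for evaluation:
#' the true CDS alignment (gene coordinates are conserved, so homologous
#' positions share columns), the true splicing-ortholog groups (transcripts
#' descending from the same ancestral transcript with no exon-skipping event
#' on the path), and the per-gene coordinates of each ancestral exon.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List of class \code{sim_family} with elements \code{models}
#'   (named list of \code{gene_model}), \code{truth} (list with \code{msa},
#'   \code{groups}, \code{exons}) and \code{config}.
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_family_impl(config))
}

simulate_family_impl <- function(config) {
  phy <- ape::read.tree(text = config$tree)
  if (is.null(phy)) stop("could not parse the newick tree")
  if (is.null(phy$edge.length)) stop("the tree needs branch lengths")
  bases <- c("A", "C", "G", "T")
  n_ex <- rand_range(config$exon_count)
  ex_lens <- 3L * vapply(seq_len(n_ex), function(i)
    rand_range(c(ceiling(config$exon_len[1] / 3), config$exon_len[2] %/% 3)),
    0L)
  in_lens <- vapply(seq_len(n_ex + 1L), function(i)
    rand_range(config$intron_len), 0L)
  starts <- integer(n_ex); pos <- 0L
  for (i in seq_len(n_ex)) {
    pos <- pos + in_lens[i]
    starts[i] <- pos + 1L
    pos <- pos + ex_lens[i]
  }
  glen <- pos + in_lens[n_ex + 1L]
  exons <- data.frame(start = starts, end = starts + ex_lens - 1L)
  root_seq <- sample(bases, glen, replace = TRUE)
  n_tr <- rand_range(config$transcripts)
  subsets <- list(seq_len(n_ex))
  tries <- 0L
  while (length(subsets) < n_tr && tries < 200L) {
    tries <- tries + 1L
    keep <- which(stats::runif(n_ex) > 0.3)  # ancestral isoform diversity
    if (length(keep) == 0L) next
    if (any(vapply(subsets, identical, TRUE, y = keep))) next
    subsets[[length(subsets) + 1L]] <- keep
  }
  group_counter <- length(subsets)
  root_tr <- lapply(seq_along(subsets), function(i)
    list(exons = subsets[[i]], group = i))

  n_tips <- length(phy$tip.label)
  root <- n_tips + 1L
  states <- vector("list", max(phy$edge))
  states[[root]] <- list(seq = root_seq, tr = root_tr)
  ## preorder over edges (parents appear before children after cladewise
  ## reordering; traverse in that order)
  edges <- ape::reorder.phylo(phy, "cladewise")$edge
  elens <- ape::reorder.phylo(phy, "cladewise")$edge.length
  for (i in seq_len(nrow(edges))) {
    par <- edges[i, 1]; child <- edges[i, 2]; L <- elens[i]
    st <- states[[par]]
    seq <- st$seq
    p_sub <- 1 - exp(-config$sub_rate * L)
    if (p_sub > 0) {
      hit <- which(stats::runif(length(seq)) < p_sub)
      if (length(hit) > 0L)
        seq[hit] <- vapply(seq[hit], function(b)
          sample(setdiff(bases, b), 1L), "")
    }
    tr <- st$tr
    p_skip <- 1 - exp(-config$skip_prob * L)
    tr <- lapply(tr, function(t) {
      if (p_skip > 0 && length(t$exons) >= 2L && stats::runif(1L) < p_skip) {
        drop <- sample(seq_along(t$exons), 1L)
        t$exons <- t$exons[-drop]
        group_counter <<- group_counter + 1L
        t$group <- group_counter
      }
      t
    })
    states[[child]] <- list(seq = seq, tr = tr)
  }
  models <- list(); groups_map <- list(); cds_group <- character(0)
  for (tip in seq_len(n_tips)) {
    label <- phy$tip.label[tip]
    st <- states[[tip]]
    cds <- list()
    for (i in seq_along(st$tr)) {
      cid <- sprintf("%s.t%d", label, i)
      cds[[cid]] <- exons[st$tr[[i]]$exons, , drop = FALSE]
      cds_group[cid] <- st$tr[[i]]$group
    }
    models[[label]] <- gene_model(label, paste(st$seq, collapse = ""), cds)
  }
  groups <- lapply(split(names(cds_group), cds_group), sort)
  groups <- unname(groups[order(vapply(groups, `[`, "", 1))])
  ## true CDS alignment on the shared gene coordinate system
  cds_ids <- sort(names(cds_group))
  idx <- cds_index(models)
  rows <- vapply(cds_ids, function(cid) {
    ch <- models[[idx[[cid]]]]$cds[[cid]]
    r <- rep("-", glen)
    p <- chain_positions(ch)
    r[p] <- strsplit(models[[idx[[cid]]]]$sequence, "")[[1]][p]
    paste(r, collapse = "")
  }, "")
  mat <- do.call(rbind, strsplit(rows, ""))
  keep_cols <- colSums(mat != "-") > 0L
  msa <- multiple_alignment(stats::setNames(vapply(seq_len(nrow(mat)),
    function(i) paste(mat[i, keep_cols], collapse = ""), ""), cds_ids))
  exon_map <- do.call(rbind, lapply(names(models), function(g)
    data.frame(gene = g, exon = seq_len(n_ex), start = exons$start,
               end = exons$end)))
  structure(list(models = models,
                 truth = list(msa = msa, groups = groups, exons = exon_map),
                 config = config),
            class = "sim_family")
}

#' Write a simulated family to disk
#'
#' Emits \code{genes.fa}, \code{models.gff3}, \code{truth_msa.fasta} (gapped)
#' and \code{truth_groups.tsv} under \code{dir}.
#'
#' @param family A \code{sim_family}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_family <- function(family, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_models(family$models, file.path(dir, "models.gff3"),
                    file.path(dir, "genes.fa"))
  write_msa_fasta(family$truth$msa, file.path(dir, "truth_msa.fasta"))
  write_orthology_groups(family$truth$groups,
                         file.path(dir, "truth_groups.tsv"))
  invisible(dir)
}
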