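# Orchestration: one config object drives feature computation, group
# statistics, classification and allosteric path analysis; every run
# records the config and seed it used so results can be reproduced
# exactly.

#' Pipeline configuration
#'
#' All cutoffs default to the values the analysis is defined with:
#' contact network 8 A (C-beta, sequence neighbours excluded), GNM 7 A,
#' ANM 13 A, dynamic residue network 6.5 A with consensus occupancy 0.5,
#' exposure classes at 5 and 30 percent RASA, significance level 0.01,
#' stratified 10-fold x 5-repeat cross-validation with 500 trees.
#'
#' @param contactCutoff,gnmCutoff,anmCutoff,drnCutoff cutoffs in A.
#' @param drnThreshold consensus occupancy threshold.
#' @param buriedMax,exposedMin RASA class boundaries (fractions).
#' @param alpha significance level for group tests.
#' @param cvFolds,cvRepeats,rfTrees classifier settings.
#' @param deltaWeighted use |energy|-aware centralities for the
#'   mutation-induced deltas (the type-swap proxy only perturbs edge
#'   energies, so the deltas are read off the weighted centralities).
#' @param seed master seed.
#' @return list of class "alloscanConfig".
#' @export
pipelineConfig <- function(contactCutoff = 8, gnmCutoff = 7,
                           anmCutoff = 13, drnCutoff = 6.5,
                           drnThreshold = 0.5, buriedMax = 0.05,
                           exposedMin = 0.30, alpha = 0.01,
                           cvFolds = 10L, cvRepeats = 5L, rfTrees = 500L,
                           deltaWeighted = TRUE, seed = 1L) {
  structure(list(contactCutoff = contactCutoff, gnmCutoff = gnmCutoff,
                 anmCutoff = anmCutoff, drnCutoff = drnCutoff,
                 drnThreshold = drnThreshold, buriedMax = buriedMax,
                 exposedMin = exposedMin, alpha = alpha,
                 cvFolds = as.integer(cvFolds),
                 cvRepeats = as.integer(cvRepeats),
                 rfTrees = as.integer(rfTrees),
                 deltaWeighted = deltaWeighted, seed = as.integer(seed)),
            class = "alloscanConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Keys absent from the file keep their defaults.
#'
#' @param path YAML file.
#' @return configuration list (see \code{\link{pipelineConfig}}).
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- pipelineConfig()
  known <- intersect(names(y), names(base))
  unknown <- setdiff(names(y), names(base))
  if (length(unknown))
    warnf("ignoring unknown config keys: %s", paste(unknown, collapse = ", "))
  base[known] <- y[known]
  do.call(pipelineConfig, base)
}

#' Serialize a configuration (plus seed) into an output directory
#'
#' @param config configuration list.
#' @param outdir directory (created if needed).
#' @return invisibly, the file path written.
#' @export
writePipelineConfig <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(outdir, "config.yaml")
  yaml::write_yaml(unclass(config), p)
  invisible(p)
}

#' Compute the full molecular-signature table for a mutation set
#'
#' Assembles all 14 feature columns: sequence entropy S_i and mean mutual
#' information at the mutated column; conservation (imported from the
#' mutation table when present, else the entropy surrogate); RASA on the
#' full assembly; ddG (imported only -- never computed here); the four
#' contact-network deltas at the mutated node (type-swap proxy unless a
#' mutant structure is supplied per mutation); and the five
#' elastic-network dynamics features read at the mutated site. Column
#' provenance ("computed" or "imported") is recorded on the table;
#' columns whose prerequisite input is missing are skipped with a
#' message.
#'
#' @param muts mutation data.frame (see \code{\link{readMutationTable}});
#'   optional columns ddG and conservation are imported.
#' @param struct wild-type \linkS4class{StructureModel}.
#' @param aln \linkS4class{SequenceAlignment}.
#' @param energies 20 x 20 contact-energy matrix; default derives one
#'   from the built-in mixing model count table
#'   (\code{\link{makeCountTable}} with the config seed).
#' @param mutantStructs optional named list of mutant structures, names
#'   "chain:position:mut_aa".
#' @param config configuration from \code{\link{pipelineConfig}}.
#' @return \linkS4class{FeatureTable}
#' @export
runFeatures <- function(muts, struct, aln, energies = NULL,
                        mutantStructs = NULL,
                        config = pipelineConfig()) {
  n <- nrow(muts)
  vals <- data.frame(row.names = seq_len(n))
  prov <- character(0)

  chk <- validateMutations(muts, aln, struct)
  if (any(!chk$ok))
    warnf("%d mutation(s) disagree with the alignment/structure wild type",
          sum(!chk$ok))

  # sequence features at the mutated column
  ent <- shannonEntropyProfile(aln)
  mim <- mutualInformationMatrix(aln)
  mmi <- meanMiPerResidue(mim)
  cols <- vapply(muts$position, function(p) alnColumnForPosition(aln, p),
                 integer(1))
  vals$S_i <- ent[cols]; prov["S_i"] <- "computed"
  vals$MI_mean <- mmi[cols]; prov["MI_mean"] <- "computed"
  if ("conservation" %in% names(muts)) {
    vals$conservation <- as.numeric(muts$conservation)
    prov["conservation"] <- "imported"
  } else {
    vals$conservation <- as.numeric(conservationSurrogate(ent)[cols])
    prov["conservation"] <- "computed"
  }

  # structure feature: RASA on the assembly
  rasa <- computeRasa(struct, buriedMax = config$buriedMax,
                      exposedMin = config$exposedMin)
  rkey <- residueKey(rasa$chain, rasa$position)
  mkey <- residueKey(muts$chain, muts$position)
  vals$RASA <- rasa$rasa[match(mkey, rkey)]; prov["RASA"] <- "computed"

  # stability: consumed as input only
  if ("ddG" %in% names(muts)) {
    vals$ddG <- as.numeric(muts$ddG); prov["ddG"] <- "imported"
  } else message("no ddG column supplied; skipping the ddG feature")

  # contact-network deltas at the mutated node
  contactDef <- list(cutoff = config$contactCutoff, representative = "cb",
                     excludeNeighbors = 1L)
  if (is.null(energies)) {
    counts <- makeCountTable(seed = config$seed, nContacts = 50000L)
    energies <- contactEnergyFromCounts(counts, pseudocount = 0.5)
  }
  wtNet <- buildAacen(struct, energies, contactDef)
  wtCent <- centralities(wtNet, weighted = config$deltaWeighted)
  deltas <- matrix(NA_real_, n, 4,
                   dimnames = list(NULL, c("dDC", "dBC", "dCC", "dC")))
  for (i in seq_len(n)) {
    ms <- mutantStructs[[paste(muts$chain[i], muts$position[i],
                               muts$mut_aa[i], sep = ":")]]
    mutNet <- suppressWarnings(
      mutateNetwork(struct, muts[i, ], energies, mutantStruct = ms,
                    contactDef = contactDef, wtNet = wtNet))
    mutCent <- centralities(mutNet, weighted = config$deltaWeighted)
    deltas[i, ] <- deltaCentrality(wtCent, mutCent, mkey[i])$signed
  }
  for (cn in colnames(deltas)) {
    vals[[cn]] <- deltas[, cn]; prov[cn] <- "computed"
  }

  # elastic-network dynamics features at the mutated site
  skey <- residueKey(struct@residues$chain, struct@residues$position)
  site <- match(mkey, skey)
  gnm <- buildGnm(struct, cutoff = config$gnmCutoff)
  gsp <- modeSpectrum(gnm)
  vals$MSF <- msf(gsp)[site]; prov["MSF"] <- "computed"
  anm <- buildAnm(struct, cutoff = config$anmCutoff)
  asp <- modeSpectrum(anm)
  pr <- prs(asp)
  vals$effectiveness <- pr$effectiveness[site]
  prov["effectiveness"] <- "computed"
  vals$sensitivity <- pr$sensitivity[site]; prov["sensitivity"] <- "computed"
  mbs <- mechanicalBridgingScore(gnm)
  vals$MBS <- mbs$MBS[site]; prov["MBS"] <- "computed"
  st <- stiffness(asp)
  vals$stiffness <- st$perResidue[site]; prov["stiffness"] <- "computed"

  front <- c("wt_aa", "position", "mut_aa", "chain", "phenotype")
  featureTable(muts[, front], vals, prov)
}

#' Group statistics, correlations and the AUC grid for a feature table
#'
#' For every feature: the three pairwise rank-sum comparisons with group
#' means; the feature-by-feature Spearman matrix; and the AUC grid over
#' the three class pairs (mild vs control, severe vs control, mild vs
#' severe), scoring by the raw feature value with the more severe class
#' as positive (both orientations recoverable as 1 - AUC).
#'
#' @param ft a \linkS4class{FeatureTable}.
#' @param config configuration (alpha is used).
#' @return list: comparisons (data.frame), spearman (matrix), auc
#'   (features x 3 matrix), config.
#' @export
runStats <- function(ft, config = pipelineConfig()) {
  pairs <- list(c("mild", "control"), c("severe", "control"),
                c("mild", "severe"))
  pairNames <- vapply(pairs, paste, "", collapse = "_vs_")
  feats <- names(featureValues(ft))
  present <- unique(as.character(mutationInfo(ft)$phenotype))
  comparisons <- list()
  auc <- matrix(NA_real_, length(feats), length(pairs),
                dimnames = list(feats, pairNames))
  usable <- vapply(pairs, function(pr) all(pr %in% present), logical(1))
  for (k in which(!usable))
    warnf("group pair %s skipped: class absent", pairNames[k])
  for (f in feats) {
    for (k in which(usable)) {
      pr <- pairs[[k]]
      comparisons[[paste(f, pairNames[k])]] <-
        tryCatch(groupCompare(ft, f, pr, alpha = config$alpha),
                 error = function(e) NULL)
      # positive = the more severe class of the pair
      sev <- pr[order(match(pr, PHENOTYPE_LEVELS))][2]
      other <- setdiff(pr, sev)
      auc[f, k] <- tryCatch(rocAuc(ft, f, sev, other)$auc,
                            error = function(e) NA_real_)
    }
  }
  list(comparisons = do.call(rbind, c(comparisons,
                                      list(make.row.names = FALSE))),
       spearman = spearmanMatrix(ft), auc = auc, config = config)
}

#' Dynamic-network path analysis of wild-type vs mutant ensembles
#'
#' Builds the dynamic residue network of each trajectory, computes
#' frame-averaged betweenness profiles, extracts the shortest paths from
#' the source to the targets on each consensus network, and compares the
#' two path sets.
#'
#' @param wtTraj,mutTraj \linkS4class{TrajectoryEnsemble} objects on the
#'   same residue set.
#' @param source node key "chain:position" (the mutation site).
#' @param targets character vector of node keys (allosteric sites).
#' @param annotations optional named character of functional-domain
#'   labels per node key.
#' @param config configuration (DRN cutoff and threshold are used).
#' @return list: wt (list: drn, bc, paths), mutant (same), comparison
#'   (data.frame from \code{\link{pathCompare}}), config.
#' @export
runPaths <- function(wtTraj, mutTraj, source, targets,
                     annotations = character(0),
                     config = pipelineConfig()) {
  analyse <- function(traj) {
    drn <- buildDrn(traj, cutoff = config$drnCutoff,
                    threshold = config$drnThreshold)
    list(drn = drn, bc = drnBetweenness(drn),
         paths = shortestPaths(drn, source, targets,
                               annotations = annotations))
  }
  wt <- analyse(wtTraj)
  mut <- analyse(mutTraj)
  list(wt = wt, mutant = mut,
       comparison = pathCompare(wt$paths, mut$paths, annotations),
       config = config)
}

#' Printed-style summary of a feature table
#'
#' The deterministic recomputation layer for deposited feature tables:
#' per-phenotype means of every feature (notably dBC and dCC), counts and
#' fractions of pathogenic (mild + severe) mutations in buried sites and
#' of control mutations at the surface under the three-class RASA rule,
#' and the fraction of mutations per class at conserved sites
#' (conservation grade above the threshold).
#'
#' @param ft a \linkS4class{FeatureTable} carrying at least RASA and/or
#'   conservation columns.
#' @param conservedAbove conservation grade threshold (default 5).
#' @param buriedMax,exposedMin RASA class boundaries.
#' @return list: group_means (features x phenotypes matrix),
#'   buried_pathogenic (count, fraction), surface_control (count,
#'   fraction), conserved_fraction (per phenotype).
#' @export
summarizeFeatureTable <- function(ft, conservedAbove = 5,
                                  buriedMax = 0.05, exposedMin = 0.30) {
  vals <- featureValues(ft)
  ph <- as.character(mutationInfo(ft)$phenotype)
  phs <- intersect(PHENOTYPE_LEVELS, unique(ph))
  gm <- sapply(phs, function(g)
    colMeans(vals[ph == g, , drop = FALSE], na.rm = TRUE))
  out <- list(group_means = gm)
  if ("RASA" %in% names(vals)) {
    rasa <- vals$RASA
    patho <- ph %in% c("mild", "severe") & !is.na(rasa)
    ctrl <- ph == "control" & !is.na(rasa)
    out$buried_pathogenic <- c(count = sum(patho & rasa < buriedMax),
                               fraction = mean(rasa[patho] < buriedMax))
    out$surface_control <- c(count = sum(ctrl & rasa > exposedMin),
                             fraction = mean(rasa[ctrl] > exposedMin))
  }
  if ("conservation" %in% names(vals)) {
    cons <- vals$conservation
    out$conserved_fraction <- vapply(phs, function(g)
      mean(cons[ph == g] > conservedAbove, na.rm = TRUE), numeric(1))
  }
  out
}
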