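#' @include io.R
NULL

.log <- function(level, fmt, ...) {
  message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

.systemTopology <- function(config) {
  switch(config$system,
    hp1Dimer = hp1DimerTopology(phosphorylated = config$phosphorylated),
    deltaCSD1 = deltaCSDTopology(1L, phosphorylated = config$phosphorylated),
    deltaCSD2 = deltaCSDTopology(2L, phosphorylated = config$phosphorylated),
    stop("unknown system: ", config$system))
}

.systemSelections <- function(config) {
  if (config$system == "hp1Dimer") {
    list(superpose = beadSelection(113, 173),
         rmsd = beadSelection(c(11, 19, 89, 102, 113),
                              c(14, 74, 91, 107, 173)))
  } else {
    list(superpose = beadSelection(19, 74),
         rmsd = beadSelection(c(11, 19, 89, 102),
                              c(14, 74, 91, 107)))
  }
}

#' Default desk-scale pipeline configuration
#'
#' The default emulates the two-molecule CSD-deletion system: an 80-member
#' synthetic mixture of 70% compact (phospho-contact-biased, kappa = 5) and
#' 30% extended (kappa = 0) conformers, a 1%-noise target profile on the
#' default q-grid, contact maps at 11 Angstrom, weighted GROMOS clustering
#' at 10 Angstrom with chain-swap-minimized RMSD (20 Angstrom and CSD
#' superposition for the dimer system), and a small genetic-algorithm
#' selection. All stage seeds derive from `seed`.
#'
#' @param outDir output directory.
#' @param seed master seed.
#' @param system `"deltaCSD2"`, `"deltaCSD1"` or `"hp1Dimer"`.
#' @return A `pipelineConfig` list.
#' @export
defaultPipelineConfig <- function(outDir = tempfile("ensaxs"), seed = 1L,
                                  system = "deltaCSD2") {
  structure(list(
    system = system,
    phosphorylated = TRUE,
    mixture = list(fractions = c(compact = 0.7, extended = 0.3),
                   kappas = c(5, 0), N = 80L),
    qGrid = list(n = 60L, qmin = 0.01, qmax = 0.30),
    noiseFrac = 0.01,
    theta = NULL,
    thetaGrid = 10^seq(-1, 4.5, length.out = 12L),
    contactCutoff = 11,
    clusterCutoff = if (system == "hp1Dimer") 20 else 10,
    chainSwap = system %in% c("hp1Dimer", "deltaCSD2"),
    ga = list(K = 10L, populationSize = 60L, generations = 120L,
              mutationRate = 0.02, crossoverRate = 0.8, elitism = 2L),
    dmaxCandidates = NULL,
    topClusters = 6L,
    seed = as.integer(seed),
    outDir = outDir
  ), class = "pipelineConfig")
}

.loadConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- defaultPipelineConfig(
    outDir = if (!is.null(config$outDir)) config$outDir else tempfile("ensaxs"),
    seed = if (!is.null(config$seed)) config$seed else 1L,
    system = if (!is.null(config$system)) config$system else "deltaCSD2")
  cfg <- utils::modifyList(base, config)
  need <- c("system", "mixture", "qGrid", "noiseFrac", "contactCutoff",
            "clusterCutoff", "seed", "outDir")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("config is missing fields: ",
                         paste(miss, collapse = ", "))
  stopifnot(cfg$noiseFrac >= 0, cfg$contactCutoff > 0, cfg$clusterCutoff > 0,
            cfg$mixture$N >= 2L)
  cfg
}

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic-ensemble analysis pipeline
#'
#' Generates the configured synthetic mixture, computes per-snapshot Debye
#' profiles and a noisy target, reweights by iterative BME (theta from an
#' L-curve scan unless fixed in the config), and characterizes the
#' reweighted ensemble: intra/inter contact maps, weighted GROMOS
#' clustering with representatives, Guinier / P(r) / Dmax analysis of the
#' target, and genetic-algorithm sub-ensemble selection with pool-versus-
#' selected Dmax distributions. All artifacts plus a machine-readable
#' manifest are written to `config$outDir`; stages log to standard error
#' and abort with the stage name on failure.
#'
#' @param config a [defaultPipelineConfig()]-style list, or the path of a
#'   YAML file with the same fields.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  cfg <- .loadConfig(config)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  out <- function(name) {
    p <- file.path(cfg$outDir, name)
    outputs <<- c(outputs, name)
    p
  }
  stage <- function(name, expr) {
    .log("INFO", "stage %s", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline failed at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  results <- list()

  results$ensemble <- stage("synthetic-ensemble", {
    top <- .systemTopology(cfg)
    spec <- mixtureSpec(cfg$mixture$fractions, cfg$mixture$kappas,
                        cfg$mixture$N, top, seed = cfg$seed)
    mix <- makeMixtureEnsemble(spec)
    writeEnsemblePDB(mix$ensemble, out("ensemble.pdb"))
    jsonlite::write_json(
      list(labels = mix$labels, counts = mix$counts,
           fractions = as.list(cfg$mixture$fractions),
           kappas = cfg$mixture$kappas, seed = cfg$seed),
      out("ground_truth.json"), auto_unbox = TRUE, digits = NA)
    mix
  })
  ens <- results$ensemble$ensemble
  N <- nConformers(ens)

  results$profiles <- stage("calc-saxs", {
    q <- defaultQGrid(cfg$qGrid$n, cfg$qGrid$qmin, cfg$qGrid$qmax)
    bases <- lapply(conformers(ens), debyeBasis, qGrid = q)
    Imat <- t(vapply(bases, function(b)
      intensities(profileFromBasis(b)), numeric(length(q))))
    target <- makeTargetProfile(
      lapply(seq_len(N), function(j) ScatteringProfile(q, Imat[j, ])),
      trueWeights = initialWeights(ens), qGrid = q,
      noiseFrac = cfg$noiseFrac, seed = cfg$seed + 17L)
    writeProfileDat(target, out("target.dat"))
    list(q = q, bases = bases, Imat = Imat, target = target)
  })
  target <- results$profiles$target

  results$reweight <- stage("reweight", {
    scan <- thetaScan(results$profiles$Imat, target, cfg$thetaGrid)
    .writeTSV(as.data.frame(scan), out("theta_scan.tsv"))
    theta <- if (is.null(cfg[["theta"]])) selectTheta(scan) else cfg[["theta"]]
    .log("INFO", "theta = %g (%s)", theta,
         if (is.null(cfg[["theta"]])) "L-curve" else "fixed")
    res <- iterativeBME(ens, target, theta, bases = results$profiles$bases)
    .writeTSV(data.frame(snapshot_id = seq_len(N),
                         w0 = sprintf("%.10e", initialWeights(ens)),
                         w = sprintf("%.10e", res@weights)),
              out("weights.tsv"))
    jsonlite::write_json(
      list(theta = theta, chi2 = res@chi2,
           chi2_reduced = res@chi2 / length(qValues(target)),
           entropy = res@entropy, phi_eff = res@phiEff,
           scale = res@scale, c1 = res@c1, c2 = res@c2),
      out("reweight.json"), auto_unbox = TRUE, digits = NA)
    list(theta = theta, scan = scan, result = res)
  })
  w <- results$reweight$result@weights
  ensW <- setEnsembleWeights(ens, w)

  results$contacts <- stage("contacts", {
    maps <- list(intra = contactProbability(ensW, cutoff = cfg$contactCutoff,
                                            mode = "intra"))
    if (length(unique(chainIds(conformers(ens)[[1L]]))) > 1L)
      maps$inter <- contactProbability(ensW, cutoff = cfg$contactCutoff,
                                       mode = "inter")
    for (nm in names(maps)) {
      m <- contactProbs(maps[[nm]])
      df <- as.data.frame(round(m, 8))
      names(df) <- maps[[nm]]@residues
      .writeTSV(cbind(residue = maps[[nm]]@residues, df),
                out(sprintf("contacts_%s.tsv", nm)))
    }
    maps
  })

  results$clusters <- stage("cluster", {
    sels <- .systemSelections(cfg)
    D <- rmsdMatrix(ens, sels$superpose, sels$rmsd,
                    chainSwap = isTRUE(cfg$chainSwap))
    cl <- gromosClusterWeighted(ensW, sels$superpose, sels$rmsd,
                                cutoff = cfg$clusterCutoff,
                                chainSwap = isTRUE(cfg$chainSwap),
                                distMatrix = D)
    .writeTSV(data.frame(snapshot_id = seq_len(N),
                         cluster = clusterLabels(cl),
                         w = sprintf("%.10e", w)),
              out("clusters.tsv"))
    reps <- representativeStructures(cl, ens,
                                     min(cfg$topClusters,
                                         length(clusterCenters(cl))))
    .writeTSV(transform(reps$summary, weight = sprintf("%.10e", weight)),
              out("cluster_summary.tsv"))
    writeEnsemblePDB(Ensemble(reps$conformers), out("representatives.pdb"))
    list(assignment = cl, representatives = reps)
  })

  results$shape <- stage("guinier-pr-dmax", {
    gu <- guinierFit(target)
    jsonlite::write_json(unclass(gu), out("guinier.json"),
                         auto_unbox = TRUE, digits = NA)
    poolDmax <- vapply(conformers(ens), conformerDmax, 0)
    cands <- if (is.null(cfg$dmaxCandidates))
      seq(0.6, 1.3, by = 0.1) * max(poolDmax) else cfg$dmaxCandidates
    scan <- dmaxScan(target, cands)
    .writeTSV(scan$table, out("dmax_scan.tsv"))
    pr <- prFromProfile(target, scan$Dmax)
    writePrCurve(pr, out("pr.dat"))
    list(guinier = gu, dmax = scan, pr = pr)
  })

  results$ga <- stage("ga-select", {
    gcfg <- gaConfig(K = cfg$ga$K, populationSize = cfg$ga$populationSize,
                     generations = cfg$ga$generations,
                     mutationRate = cfg$ga$mutationRate,
                     crossoverRate = cfg$ga$crossoverRate,
                     elitism = cfg$ga$elitism, seed = cfg$seed + 31L)
    sel <- gaSelect(results$profiles$Imat, target, gcfg)
    .writeTSV(data.frame(rank = seq_along(sel$selected),
                         snapshot_id = sel$selected),
              out("ga_selected.tsv"))
    .writeTSV(data.frame(generation = seq_along(sel$trace),
                         best_chi2 = sel$trace), out("ga_trace.tsv"))
    rep_ <- distributionReport(ens, sel$selected, metric = "Dmax")
    .writeTSV(data.frame(mid = rep_$mids, pool = rep_$before,
                         selected = rep_$after), out("ga_dmax_hist.tsv"))
    c(sel, list(distribution = rep_))
  })

  manifest <- list(
    package = "ensaxs",
    version = as.character(utils::packageVersion("ensaxs")),
    config = cfg[setdiff(names(cfg), "outDir")],
    seeds = list(master = cfg$seed, target = cfg$seed + 17L,
                 ga = cfg$seed + 31L),
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log("INFO", "pipeline complete: %d artifacts in %s",
       length(outputs) + 1L, cfg$outDir)
  invisible(c(results, list(manifest = manifest, outDir = cfg$outDir)))
}
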