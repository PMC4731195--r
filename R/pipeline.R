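# End-to-end orchestration: search -> matrix -> direct pairs ->
# indirect pairs -> statistics, with deterministic on-disk outputs.

.logLines <- function(env, stage, level, msg) {
    line <- sprintf("[%s] %s: %s", level, stage, msg)
    env$lines <- c(env$lines, line)
    message(format(Sys.time(), "%H:%M:%S "), line)
    invisible(line)
}

#' Default pipeline configuration
#'
#' @param proteomeFasta,annotationFile,complexFile,modelFile,catalogFile
#'   input paths (complex/model/catalog optional: NULL disables complex
#'   expansion and the indirect stage).
#' @param outDir output directory.
#' @param scopeOrganism organism id whose genes are the prediction
#'   scope (targets and replacers); NULL = all organisms.
#' @param rounds round schedule, see [defaultRounds()].
#' @param media c(minimal, rich) medium names.
#' @param growthEpsilon growth threshold for the indirect stage.
#' @param seed integer seed recorded in the config snapshot (the
#'   pipeline itself is deterministic; the seed matters when the inputs
#'   are generated).
#' @return A config list.
#' @export
pipelineConfig <- function(proteomeFasta, annotationFile, outDir,
                           complexFile = NULL, modelFile = NULL,
                           catalogFile = NULL, scopeOrganism = NULL,
                           rounds = defaultRounds(),
                           media = c("M9", "rich"),
                           growthEpsilon = 1e-6, seed = 1L) {
    list(proteome_fasta = proteomeFasta,
         annotation_file = annotationFile,
         complex_file = complexFile, model_file = modelFile,
         catalog_file = catalogFile, out_dir = outDir,
         scope_organism = scopeOrganism, rounds = rounds,
         media = media, growth_epsilon = growthEpsilon,
         seed = as.integer(seed))
}

.configSnapshot <- function(config) {
    snap <- config
    snap$rounds <- lapply(config$rounds, function(rc) list(
        max_uncovered = rc@criteria@maxUncovered,
        min_coverage = rc@criteria@minCoverage,
        min_identity = rc@criteria@minIdentity,
        min_positives = rc@criteria@minPositives,
        cluster_identity = rc@clusterIdentity,
        trim_occupancy = rc@trimOccupancy))
    snap
}

#' Run the full prediction pipeline
#'
#' Stages: load inputs; build a gene tree for every in-scope metabolic
#' gene; assemble the promiscuity matrix (with complex expansion when
#' complex definitions are given); predict direct pairs and their
#' statistics (replacers per target, reciprocal pairs); when a model
#' and catalog are given, classify the model's in-scope genes and
#' predict indirect pairs by growth rescue. All outputs (trees JSON,
#' matrix, pair tables, statistics, log, config snapshot) are written
#' to \code{config$out_dir} and are byte-identical across reruns with
#' the same inputs and config. Any stage error aborts with the stage
#' name attached.
#'
#' @param config a [pipelineConfig()] list.
#' @return Invisibly, a list with the in-memory results (proteome,
#'   trees, matrix, direct, indirect, rescues, stats, outputs).
#' @export
runPipeline <- function(config) {
    log <- new.env(parent = emptyenv())
    log$lines <- character()
    outDir <- config$out_dir
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    stage <- function(name, code) {
        tryCatch(code, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }

    catalog <- NULL
    if (!is.null(config$catalog_file))
        catalog <- stage("load", loadReactionCatalog(config$catalog_file))
    proteome <- stage("load", loadProteome(config$proteome_fasta,
                                           config$annotation_file,
                                           catalog = NULL))
    complexes <- NULL
    if (!is.null(config$complex_file))
        complexes <- stage("load", loadComplexes(config$complex_file))
    model <- NULL
    if (!is.null(config$model_file))
        model <- stage("load", loadModel(config$model_file))
    ann <- annotations(proteome)
    scope <- if (is.null(config$scope_organism)) ann$gene_id
             else ann$gene_id[ann$organism_id %in% config$scope_organism]
    roots <- sort(intersect(intersect(scope, metabolicGenes(proteome)),
                            geneIds(proteome)))
    .logLines(log, "load", "INFO", sprintf(
        "%d sequences, %d in-scope metabolic root gene(s)",
        length(proteome), length(roots)))

    trees <- stage("search", lapply(roots, function(g)
        iterateSearch(g, proteome, rounds = config$rounds)))
    names(trees) <- roots
    .logLines(log, "search", "INFO", sprintf(
        "%d tree(s); %d with recruited homolog(s)", length(trees),
        sum(vapply(trees, function(t) nrow(t@members) > 1L, NA))))

    pm <- stage("matrix", buildMatrix(trees, proteome, complexes))
    .logLines(log, "matrix", "INFO", sprintf(
        "%d promiscuous entr(y/ies)", nrow(matrixEntries(pm))))

    direct <- stage("direct", predictDirectPairs(pm, scope = scope))
    rpt <- replacersPerTarget(direct)
    recip <- findReciprocal(direct)
    .logLines(log, "direct", "INFO", sprintf(
        "%d direct pair(s), %d reciprocal", nrow(direct), nrow(recip)))

    indirect <- emptyPairs()
    rescues <- .emptyRescues()
    if (!is.null(model) && !is.null(catalog)) {
        targets <- intersect(modelGenes(model), scope)
        res <- stage("indirect", suppressMessages(
            predictIndirectPairs(model, pm, catalog, targets,
                                 scope = scope, media = config$media,
                                 growthEpsilon = config$growth_epsilon)))
        indirect <- res$pairs
        rescues <- res$rescues
        .logLines(log, "indirect", "INFO", sprintf(
            "%d target(s) tested, %d indirect pair(s)",
            length(unique(rescues$target_gene)), nrow(indirect)))
    } else {
        .logLines(log, "indirect", "INFO",
                  "skipped (no model/catalog configured)")
    }

    outputs <- c(
        trees = writeGeneTrees(trees, file.path(outDir, "trees.json"),
                               file.path(outDir, "trees.nwk")),
        matrix = writePromiscuityMatrix(pm, file.path(outDir,
                                                      "matrix.tsv")),
        direct = writePairs(direct, file.path(outDir,
                                              "direct_pairs.tsv")),
        indirect = writePairs(indirect, file.path(outDir,
                                                  "indirect_pairs.tsv")),
        rescues = .writeTsv(rescues, file.path(outDir, "rescues.tsv")),
        histogram = .writeTsv(rpt$histogram,
                              file.path(outDir,
                                        "replacers_per_target.tsv")),
        reciprocal = .writeTsv(recip, file.path(outDir,
                                                "reciprocal_pairs.tsv")))
    yaml::write_yaml(.configSnapshot(config),
                     file.path(outDir, "config.yaml"))
    writeLines(log$lines, file.path(outDir, "log.txt"))
    invisible(list(proteome = proteome, trees = trees, matrix = pm,
                   direct = direct, indirect = indirect,
                   rescues = rescues,
                   stats = list(replacersPerTarget = rpt,
                                reciprocal = recip),
                   outputs = outputs))
}
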