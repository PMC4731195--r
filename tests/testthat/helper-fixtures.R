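# Shared in-code fixtures for the indirect-prediction and acceptance
# tests.

toy_matrix <- function() {
    # one gene per catalog function, plus a native-function entry that
    # must be excluded
    entries <- data.frame(
        root_gene = c("org1_g005", "org1_g006", "org1_g007",
                      "org1_g009", "org1_g010"),
        function_id = c("fn_p5ps", "fn_decoy_deadend",
                        "fn_decoy_duplicate", "fn_decoy_unknown",
                        "fn_native"),
        evidence_gene = "ev", evidence_organism = "shi",
        identity = c(0.4, 0.45, 0.45, 0.5, 0.5),
        positives = 0.6, coverage = 0.9, stringsAsFactors = FALSE)
    genes <- paste0("org1_g0", c("05", "06", "07", "09", "10", "19",
                                 "20", "21", "22", "23"))
    primaries <- data.frame(gene_id = genes,
                            function_id = paste0("fn_of_", genes),
                            stringsAsFactors = FALSE)
    primaries$function_id[primaries$gene_id == "org1_g010"] <-
        "fn_primary10"
    primaries <- rbind(primaries,
                       data.frame(gene_id = "org1_g011",
                                  function_id = "fn_native"))
    new("PromiscuityMatrix", entries = entries, primaries = primaries,
        geneInfo = data.frame(gene_id = unique(primaries$gene_id),
                              organism_id = "org1",
                              is_metabolic = TRUE,
                              stringsAsFactors = FALSE))
}
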