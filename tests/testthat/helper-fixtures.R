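# Shared fixtures, generated in code.

# two one-hot repertoires on a shared 2-feature universe
oneHotCounts <- function(n = 20L) {
    m <- rbind(rep_a = c(n, 0L), rep_b = c(0L, n))
    colnames(m) <- c("V1", "V2")
    RepertoireCounts(m, featureName = "v_gene", repertoiresAsRows = TRUE)
}

# small AIRR-style TSV on disk; returns the path
writeAirrFixture <- function(path = tempfile(fileext = ".tsv")) {
    writeLines(c(
        "repertoire_id\tv_call\tj_call",
        "s1\tIGHV1-2*02\tIGHJ4*02",
        "s1\tIGHV1-2*04\tIGHJ4*02",
        "s1\tIGHV3-23*01\tIGHJ6*01",
        "s1\tIGHV1-2*02,IGHV1-2*04\tIGHJ4*02",
        "s2\tIGHV3-23*01\tIGHJ6*01",
        "s2\tIGHV1-2*02,IGHV3-23*01\tIGHJ4*02"
    ), path)
    path
}

# path to the installed CLI script and a runner returning status + output
cliPath <- function() {
    p <- system.file("scripts", "rdi_tool.R", package = "RDItools")
    stopifnot(nzchar(p))
    p
}

runCli <- function(...) {
    rscript <- file.path(R.home("bin"), "Rscript")
    out <- suppressWarnings(system2(rscript, c(cliPath(), ...),
        stdout = TRUE, stderr = TRUE))
    status <- attr(out, "status")
    list(status = if (is.null(status)) 0L else status,
         output = paste(out, collapse = "\n"))
}
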