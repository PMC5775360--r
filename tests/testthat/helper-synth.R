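# Shared simulation configs for tests. The small config keeps pipeline-level
# tests fast; empty layouts give bare quadripartite genomes.

empty_ssr_layout <- function() default_ssr_layout()[0L, , drop = FALSE]
empty_repeat_layout <- function() default_repeat_layout()[0L, , drop = FALSE]
empty_hotspot_layout <- function() default_hotspot_layout()[0L, , drop = FALSE]

# bare quadripartite genome with no planted elements
bare_sim_config <- function(seed, lsc = 2000L, ir = 600L, ssc = 800L) {
  sim_config(seed = seed, lsc_len = lsc, ir_len = ir, ssc_len = ssc,
             genes = list(), ssrs = empty_ssr_layout(),
             repeats = empty_repeat_layout(), tree = default_tree(),
             hotspots = empty_hotspot_layout())
}

# 7.9 kb plastome with a reduced layout (fast pipeline runs)
small_sim_config <- function(seed = 7L) {
  genes <- list(
    gene_feature("trnH", "tRNA", 30L, 110L),
    gene_feature("psbA", "CDS", 150L, 550L),
    gene_feature("matK", "CDS", 1700L, 2300L),
    gene_feature("rps19", "CDS", 3900L, 4179L),   # crosses LSC/IRa (100|179)
    gene_feature("ndhF", "CDS", 5150L, 5750L, "-"),  # crosses IRa/SSC (50|550)
    gene_feature("ycf1", "CDS", 6000L, 7000L))       # crosses SSC/IRb (700|300)
  ssrs <- data.frame(
    motif = c("A", "AT", "AAT"), units = c(12L, 7L, 4L),
    pos = c(600L, 1000L, 1850L), region = "LSC",
    context = c("IGS", "IGS", "CDS"), gene = c("", "", "matK"),
    stringsAsFactors = FALSE)
  repeats <- data.frame(type = c("F", "P"), length = c(40L, 45L),
                        mismatches = c(0L, 2L), pos1 = c(700L, 2900L),
                        pos2 = c(2600L, 3400L), stringsAsFactors = FALSE)
  hotspots <- data.frame(start = c(1200L, 5300L), end = c(1800L, 5900L))
  sim_config(seed = seed, lsc_len = 4000L, ir_len = 1200L, ssc_len = 1500L,
             genes = genes, ssrs = ssrs, repeats = repeats,
             tree = default_tree(), hotspots = hotspots)
}

# write a bundle's pipeline inputs to a temp dir and build the config
pipeline_config_for <- function(bundle, out_dir,
                                in_dir = tempfile("plastidkit-in-")) {
  write_dataset(bundle, in_dir)
  pipeline_config(genomes = file.path(in_dir, "genomes.fasta"),
                  features = file.path(in_dir, "features.gff3"),
                  alignment = file.path(in_dir, "alignment.fasta"),
                  reference = bundle$tree$tip.label[1L],
                  out_dir = out_dir)
}
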