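Package: gmsmap
Title: Genetic Model Discrimination and Linkage Mapping of Genic Male Sterility
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the genetic analysis of genic male sterility (GMS) in
    Brassica crops: discrimination of a one-locus multi-allelic dominance
    series versus a two-gene (sterility plus restorer) epistatic model by
    likelihood over structured progeny tests; simulation of F2 and BC1 mapping
    populations with genotyping-by-sequencing style marker noise (read depth,
    missingness, heterozygote dropout); two-point linkage analysis with
    Kosambi distances, LOD-gated grouping, marker ordering, recombination-bin
    construction and trait placement; and recombinant-based fine mapping with
    cosegregation testing of candidate markers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
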