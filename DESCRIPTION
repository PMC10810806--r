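Package: morbclust
Title: Co-Occurrence Clustering of Chronic Disease Patterns in Multimorbid
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Identifies patterns of chronic diseases that tend to co-occur
    in multimorbid patients from a binary patient-by-disease matrix.
    Diseases are compared with the Jaccard co-occurrence distance,
    embedded in two dimensions by t-distributed stochastic neighbour
    embedding, and grouped by a fuzzy k-means algorithm with membership
    thresholding, elbow and silhouette cluster-count selection, recursive
    sub-clustering, and prevalence reporting stratified by sex and age
    class.  A synthetic multimorbid cohort generator with planted
    co-occurrence blocks supports validation when real administrative
    data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
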