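Package: swineNE
Title: Net Energy Evaluation of Pig Feed Ingredients by Indirect Calorimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the complete energy evaluation of feed ingredients in
    growing pigs from respiration-chamber records: heat production by the
    Brouwer equation, apparent total tract digestibility and nitrogen
    balance, diet-level digestible, metabolizable and net energy (DE/ME/NE)
    partition with covariance adjustment of heat production to a reference
    metabolizable-energy intake, ingredient-level net energy by the
    difference method with the measured-GE ratio correction, Noblet-type NE
    prediction equations with relative-error validation, Pearson correlation
    screens and stepwise regression for composition-based NE prediction. A
    respiration-chamber simulator with known ground truth makes every stage
    testable without animal data, and a packaged reference dataset of six
    wheat bran samples and one wheat shorts supports worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, tools, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
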