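Package: myofuse
Title: Automated Quantification of Myotube Area and Nuclear Fusion Index
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments immunofluorescence-stained myotube cultures from
    bi- or tri-channel TIFF images (a cytoskeletal marker channel such as
    desmin or myosin heavy chain, and a DAPI nuclear channel), counts
    nuclei inside and outside myotubes, excludes mononucleated myoblasts
    by an in-border nucleus-count rule, and reports myotube surface area
    and the nuclear fusion index (NFI). Nuclei are detected by adaptive
    noise filtering, automatic thresholding and morphological cleaning,
    with rounded nuclei located by a circle Hough transform and clustered
    nuclei split by marker-controlled watershed on the distance
    transform. Includes diagnostic overlay images, a batch command-line
    interface, and a seeded synthetic-culture generator with exact ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    png,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
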