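#!/usr/bin/env Rscript
## Gel-quantification arithmetic on synthetic example intensities
## (inputs below are invented demonstration values, not measured gels).
## CHEF lanes: background from a section above the well is subtracted from
## well and lane, and the well fraction = corrected well / corrected total.
## 2D gels: the bubble:1N ratio indexes initiation within the restriction
## fragment, and the induced/uninduced relative ratio expresses residual
## initiation as a fraction of the control.

suppressMessages(library(originfire))
dir.create("results", showWarnings = FALSE)

chef_path <- "results/chef_lanes_synthetic.csv"
writeLines(c("sample,time,well,lane,background",
             "uninduced,30,42,70,10",
             "uninduced,60,55,58,10",
             "uninduced,100,28,92,10",
             "induced,30,48,62,10",
             "induced,60,68,44,10",
             "induced,100,66,46,10"), chef_path)
chef <- quantify_chef_csv(chef_path, "results/chef_well_fractions.csv")
message("CHEF well fractions (synthetic example lanes):")
print(chef, digits = 3)

gel2d_path <- "results/gel2d_regions_synthetic.csv"
writeLines(c("sample,time,bubble,one_n",
             "uninduced,30,12,100",
             "uninduced,60,8,100",
             "induced,30,0.6,100",
             "induced,60,0.4,100"), gel2d_path)
g2 <- quantify_2d_csv(gel2d_path, reference_sample = "uninduced",
                      out_path = "results/gel2d_bubble_ratios.csv")
message("bubble:1N ratios and the induced/uninduced relative form:")
print(g2, digits = 3)
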