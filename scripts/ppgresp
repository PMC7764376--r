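#!/usr/bin/env Rscript
# thin shell wrapper over ppgresp::ppg_cli()
quit(save = "no",
     status = ppgresp::ppg_cli(commandArgs(trailingOnly = TRUE)))
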