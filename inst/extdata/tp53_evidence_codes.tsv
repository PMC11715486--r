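variant_hgvs_c	codes
c.782G>C	PM2_Supporting
c.782G>T	PM2_Supporting
c.672G>C	PM2_Supporting
c.672G>T	PM2_Supporting
c.671A>C	PM2_Supporting
c.671A>T	PM2_Supporting
c.559G>A	PM2_Supporting
c.559G>C	PM2_Supporting
c.410T>A	PM2_Supporting
c.356C>G	PM2_Supporting;PS4_Supporting
c.318C>G	PM2_Supporting
c.182A>G	PM2_Supporting;PP4
c.178C>A	PM2_Supporting
c.50A>T	PM2_Supporting
c.314G>T	PM2_Supporting
c.817C>A	PM2_Supporting;PS4_Supporting;PS3;PP3_Moderate;PM1
c.811G>A	PM2_Supporting;PS3_Moderate;PP3;PM1;PP4
c.797G>T	PM2_Supporting;PS3;PP3_Moderate;PM1
c.374C>G	PM2_Supporting;PS4_Supporting;PS3;PP3_Moderate;PM1_Supporting
c.325T>A	PM2_Supporting;PS4_Supporting;PS3
c.919G>T	PM2_Supporting;BS3;BP4_Moderate
c.781A>C	PM2_Supporting;BS3;BP4
c.781A>G	PM2_Supporting;BS3;BP4_Moderate
c.673G>C	PM2_Supporting;BS3;BP4_Moderate
c.837G>C	PM2_Supporting
c.837G>T	PM2_Supporting
c.816G>A	PM2_Supporting
c.114A>G	PM2_Supporting
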