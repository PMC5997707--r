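# Synthetic photophysics profile for the hyBRET emitter set.
# The measured constants of the original study are not publicly
# deposited; these are literature-typical values for the emitter
# classes involved, with phi_CNL chosen consistent with the published
# luciferase-to-CFP BRET efficiency of the cyan Nano-lantern fusion
# (E_RC = 0.13). See the methods vignette.
phi_C: 0.84        # Turquoise-family CFP quantum yield
phi_Y: 0.77        # YPet-family YFP quantum yield
phi_R: 0.053       # RLuc8 bioluminescence quantum yield
phi_N: 0.20        # NanoLuc bioluminescence quantum yield (stand-in)
phi_CNL: 0.15531   # cyan Nano-lantern (RLuc8-CFP fusion) quantum yield
eps_ratio: 4.2     # eps_Y,max / eps_C(lambda_ex), relative units
cross_excitation_fraction: 0.029  # eps_Y(440 nm) / eps_Y(513 nm)
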