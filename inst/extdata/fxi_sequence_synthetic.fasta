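>FXI_synthetic 625-residue FXI-like stand-in (SYNTHETIC): residue identities named in the source placed at their HGVS positions, deterministic filler elsewhere; not the F11 reference translation
MVLSGTEKIRDNQHPAVLECTEKIRDNQCPAVLSGTEVIRPNQHPCVLSCTEKIRCNQHP
AVLVGTEKIRDNQHPCVLSGTEKIRDNQHPAVLSGTGKIADNCHPQVLSCTEKIRDNQHP
AVLSGTEKIRDNQHECVLSCTEKIRCNQHPYVLSGTEKIRDRQHCAVLSGTEKIRDNQHP
AVLSGTEKIRDNCHPAVLSCTEKIRDNQHPAVLSGTEKIRDNQHPCVLSCTEKIRCNQHP
AVLSGWEKIRDNQHCAVLSGTEKIRDNRHPAVLSGTEKIRQNCHPAVLSGCEKIRDNQHP
FLLSETDIVRDNQHPACLSGCEKIRRCQHPAVTSGTEKCNDNQHKCYLKGTEKIRDTQHL
AVRSGTEGIRDNQCPAVLSCTEKIRDRIHPAVLSGREKIRDNQHPAVLSGTEKIRCNQHP
AVLSWTEKIRHCQHPAVLSGTERIYDNQHPAVLSGTEKIRDNQHPAVLSGTEKIRDNQHD
AVLSGTEKIRDNQHPAVLSCTEKIRDNQHPAVLCWTEKWRYNQHPAVLSGTEKIRDNQHP
AVLSCTEKIRDNQHPAVLSCTEKIRDNQHPCVLSSTEKIRCNQHPAVLSGTEKIRGNQCP
AVLSGTEKIRDNQHPAVLSGTTKIR
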