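# synthetic example table (randomly generated scores, not measured propensities)
A C D E F G H I K L M N P Q R S T V W Y
helix 1.232 0.967 0.745 0.827 0.915 1.714 0.725 0.936 1.019 1.024 0.809 1.142 1.268 0.719 0.618 1.763 1.377 0.921 0.773 0.681
strand 0.649 0.766 0.665 0.849 0.914 1.280 1.318 0.573 2.145 1.295 1.069 1.076 0.700 0.629 1.131 1.329 1.186 0.689 0.912 1.055
other 1.057 0.366 1.046 0.747 0.361 1.091 0.877 1.797 1.998 1.994 0.903 1.593 1.260 1.365 0.716 0.851 0.626 1.197 0.610 0.671
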