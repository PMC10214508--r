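{"lambda": [0.0001, 0.00011231, 0.000126136, 0.000141664, 0.000159104, 0.00017869, 0.000200688, 0.000225393, 0.00025314, 0.000284303, 0.000319302, 0.00035861, 0.000402756, 0.000452337, 0.000508022, 0.000570562, 0.0006408, 0.000719686, 0.000808282, 0.000907785, 0.00101954, 0.00114505, 0.00128601, 0.00144432, 0.00162212, 0.00182181, 0.00204609, 0.00229797, 0.00258086, 0.00289858, 0.00325541, 0.00365616, 0.00410625, 0.00461175, 0.00517947, 0.00581709, 0.0065332, 0.00733747, 0.00824074, 0.00925522, 0.0103946, 0.0116742, 0.0131113, 0.0147254, 0.0165382, 0.0185741, 0.0208606, 0.0234287, 0.0263129, 0.0295521, 0.0331901, 0.0372759, 0.0418648, 0.0470185, 0.0528067, 0.0593074, 0.0666085, 0.0748083, 0.0840175, 0.0943604, 0.105977, 0.119023, 0.133675, 0.150131, 0.168613, 0.18937, 0.212682, 0.238864, 0.26827, 0.301295, 0.338386, 0.380042, 0.426827, 0.479372, 0.538384, 0.604662, 0.679099, 0.762699, 0.85659, 0.96204, 1.08047, 1.21348, 1.36287, 1.53064, 1.71907, 1.9307, 2.16838, 2.43531, 2.73511, 3.07181, 3.44997, 3.87468, 4.35167, 4.88737, 5.48903, 6.16476, 6.92367, 7.776, 8.73326, 9.80837, 11.0158, 12.3719, 13.895, 15.6055, 17.5266, 19.6842, 22.1074, 24.8289, 27.8855, 31.3183, 35.1737, 39.5038, 44.3669, 49.8286, 55.9628, 62.852, 70.5894, 79.2793, 89.0389, 100.0]}
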