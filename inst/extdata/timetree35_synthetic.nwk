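((((((t01:240.7105771,(t02:219.2349327,(t03:191.1685672,(((t04:5.063044161,t05:5.063044161):86.70305554,(t06:69.71511662,t07:69.71511662):22.05098308):29.62132493,t08:121.3874246):69.78114255):28.06636553):21.4756444):114.0340512,((t09:165.3428021,((t10:38.37815307,t11:38.37815307):8.075391371,t12:46.45354444):118.8892577):49.03261464,((t13:23.6779041,t14:23.6779041):46.46345752,t15:70.14136162):144.2340552):140.3692115):143.3000591,(((t16:182.9439974,((t17:39.70996703,(t18:38.80694051,t19:38.80694051):0.903026521):119.6251738,t20:159.3351408):23.60885659):67.43403776,(t21:97.24329506,t22:97.24329506):153.1347401):88.71260144,((t23:67.02154178,t24:67.02154178):209.7171681,t25:276.7387099):62.3519267):158.9540508):39.92445048,((t26:36.00312576,t27:36.00312576):43.92341138,t28:79.92653714):458.0426007):112.9558941,(t29:629.9963047,t30:629.9963047):20.92872721):49.07496809,((t31:365.3373409,((t32:107.5461044,t33:107.5461044):171.4032571,t34:278.9493616):86.38797937):315.7183189,t35:681.0556598):18.94434016):20;
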